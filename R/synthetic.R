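# Seeded simulation of spectral-tuning landscapes with the statistical
# structure the decomposition assumes: near-zero main effects, sparse
# large epistatic interactions, optional nonfunctional genotypes, and
# i.i.d. Gaussian measurement noise (the V = I assumption).

#' Generate a synthetic phenotype landscape with known ground truth
#'
#' Draws an effect table theta (main effects from a normal distribution;
#' each interaction of order >= 2 nonzero with probability
#' `interaction_prob`, magnitude `interaction_min` plus an exponential
#' excess, random sign), builds the noiseless lambda of every genotype as
#' `lambda_anc + sum(theta)`, adds Gaussian measurement noise, and
#' withholds the lambda of nonfunctional genotypes.
#'
#' Defaults emulate the spectral-tuning setting: 7 sites around a 357 nm
#' UV ancestor, main effects of a couple of nm, roughly one interaction in
#' six carrying |theta| >= 5 nm, and unit-variance measurement noise.
#'
#' Random draws occur in a fixed documented order (mains; then per
#' interaction subset, in size-then-mask order, an inclusion draw, a sign
#' and a magnitude; then random nonfunctional marks; then one noise draw
#' per genotype, ancestor first), so outputs are reproducible under a
#' seed across versions.
#'
#' @param L number of sites (default 7).
#' @param lambda_anc ancestral phenotype in nm (default 357).
#' @param main_mean,main_sd normal parameters of the single-site effects
#'   (defaults 0 and 2 nm).
#' @param interaction_prob probability that an interaction term is nonzero
#'   (default 0.175).
#' @param interaction_min,interaction_mean_excess nonzero interaction
#'   magnitudes are `interaction_min + Exp(mean = interaction_mean_excess)`
#'   nm with random sign (defaults 5 and 5).
#' @param nonfunctional explicit nonfunctional genotypes (vector of masks
#'   or "+"-joined label strings over sites `s1..sL`), or `NULL`.
#' @param nonfunctional_prob if `nonfunctional` is `NULL`, each non-ancestor
#'   genotype is independently nonfunctional with this probability
#'   (default 0).
#' @param noise_sd SD of the additive measurement noise in nm (default 1).
#' @param fix_anchor logical; `FALSE` (default) also perturbs the ancestral
#'   measurement, matching the identity-variance error model.
#' @param sites optional site labels; default `s1..sL`.
#' @param seed integer seed (mandatory: every landscape is reproducible).
#' @return list with `landscape` (a [landscape()]) and `truth` (list with
#'   `theta` — numeric by genotype mask, index `mask + 1` —,
#'   `lambda_true`, and `nonfunctional` masks).
#' @examples
#' sim <- generate_landscape(L = 3, noise_sd = 0, seed = 1)
#' fit <- decompose(sim$landscape)
#' all.equal(fit$effects$theta, sim$truth$theta[fit$effects$mask + 1])
#' @export
generate_landscape <- function(L = 7L, lambda_anc = 357, main_mean = 0,
                               main_sd = 2, interaction_prob = 0.175,
                               interaction_min = 5,
                               interaction_mean_excess = 5,
                               nonfunctional = NULL, nonfunctional_prob = 0,
                               noise_sd = 1, fix_anchor = FALSE,
                               sites = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nonfunctional_prob >= 0, nonfunctional_prob <= 1, noise_sd >= 0,
            interaction_prob >= 0, interaction_prob <= 1)
  if (is.null(sites)) sites <- paste0("s", seq_len(L))
  stopifnot(length(sites) == L)
  n <- 2L^L
  set.seed(as.integer(seed))
  theta <- numeric(n)
  masks <- lattice_order(L)[-1L]
  sz <- popcount(masks)
  theta[masks[sz == 1L] + 1L] <- stats::rnorm(L, main_mean, main_sd)
  for (m in masks[sz >= 2L]) {
    on <- stats::runif(1) < interaction_prob
    sign <- sample(c(-1, 1), 1L)
    mag <- interaction_min + stats::rexp(1, 1 / interaction_mean_excess)
    if (on) theta[m + 1L] <- sign * mag
  }
  lambda_true <- vapply(0:(n - 1L), function(m)
    lambda_anc + sum(theta[submasks(m) + 1L]), numeric(1L))
  if (!is.null(nonfunctional)) {
    nf <- vapply(nonfunctional, genotype_mask, integer(1L), sites = sites)
    if (any(nf == 0L)) stop("ancestor cannot be nonfunctional")
  } else if (nonfunctional_prob > 0) {
    nf <- (1:(n - 1L))[stats::runif(n - 1L) < nonfunctional_prob]
  } else {
    nf <- integer(0)
  }
  noise <- stats::rnorm(n, 0, noise_sd)
  if (fix_anchor) noise[1L] <- 0
  lambda <- lambda_true + noise
  functional <- rep(TRUE, n)
  functional[nf + 1L] <- FALSE
  lambda[nf + 1L] <- NA_real_
  ls <- landscape(sites, lambda[1L], lambda = lambda,
                  functional = functional)
  list(landscape = ls,
       truth = list(theta = theta, lambda_true = lambda_true,
                    nonfunctional = sort(as.integer(nf))))
}

#' The three-site long-wavelength pigment fixture (human M)
#'
#' The 8-genotype landscape of the ancestral long-wavelength-sensitive
#' pigment (lambda_anc = 560 nm) under the mutations S180A, Y277F and
#' T285A, whose joint effect of -29 nm produced the 530 nm middle-
#' wavelength pigment. All genotypes are functional; the lambdas encode
#' the known effect terms (-5, -10, -17 for the singles; 0, -2, 1 for the
#' pairs; 4 for the triple).
#'
#' @return a complete [landscape()] over `c("S180A", "Y277F", "T285A")`.
#' @examples
#' decompose(human_m_fixture())$effects
#' @export
human_m_fixture <- function() {
  sites <- c("S180A", "Y277F", "T285A")
  theta <- numeric(8)
  theta[genotype_mask("S180A", sites) + 1L] <- -5
  theta[genotype_mask("Y277F", sites) + 1L] <- -10
  theta[genotype_mask("T285A", sites) + 1L] <- -17
  theta[genotype_mask("S180A+Y277F", sites) + 1L] <- 0
  theta[genotype_mask("S180A+T285A", sites) + 1L] <- -2
  theta[genotype_mask("Y277F+T285A", sites) + 1L] <- 1
  theta[genotype_mask("S180A+Y277F+T285A", sites) + 1L] <- 4
  lambda <- vapply(0:7, function(m) 560 + sum(theta[submasks(m) + 1L]),
                   numeric(1L))
  landscape(sites, 560, lambda = lambda, functional = rep(TRUE, 8))
}

#' A synthetic seven-site spectral-tuning instance (s1-like)
#'
#' A fixed, fully synthetic 7-site landscape shaped like the short-
#' wavelength pigment system — a 357 nm UV ancestor, a 411 nm blue
#' endpoint, printed-scale main effects, four large interactions, a
#' mutation that is lethal when it occurs first (T52F-like), and a second
#' nonfunctional genotype — together with a 15-taxon mammalian-shaped
#' time-annotated tree and character matrix from which parsimony recovers
#' a four-group branch order admitting exactly eight trajectories.
#'
#' This is NOT measured data: the interaction terms and the tree topology
#' are constructed so that every stage of the pipeline (imputation,
#' termination, constrained enumeration, substitution ordering) is
#' exercised end-to-end with realistic magnitudes.
#'
#' @return list with `landscape`, `truth` (generating theta by mask and the
#'   nonfunctional masks), `partial_order` (the four branch groups),
#'   `tree` (`ape::phylo`, rooted, 15 tips), `characters` (15 x 7 matrix of
#'   amino-acid states), `ages` (data frame of node ages in My along the
#'   focal lineage), and `focal_tip` (`"Human"`).
#' @examples
#' fx <- s1_like_fixture()
#' count_accessible(fx$landscape)
#' @export
s1_like_fixture <- function() {
  sites <- c("F46T", "F49L", "T52F", "F86L", "T93P", "A114G", "S118T")
  n <- 2L^7L
  theta <- numeric(n)
  mains <- c(F46T = -2, F49L = -3, T52F = 0, F86L = 0, T93P = 2,
             A114G = 1, S118T = 1)
  for (s in names(mains)) theta[genotype_mask(s, sites) + 1L] <- mains[[s]]
  theta[genotype_mask(c("T93P", "A114G"), sites) + 1L] <- 20
  theta[genotype_mask(c("F86L", "T93P"), sites) + 1L] <- 20
  theta[genotype_mask(c("F49L", "S118T"), sites) + 1L] <- 8
  theta[genotype_mask(c("F46T", "T52F"), sites) + 1L] <- 7
  lambda <- vapply(0:(n - 1L), function(m) 357 + sum(theta[submasks(m) + 1L]),
                   numeric(1L))
  nf <- c(genotype_mask("T52F", sites),
          genotype_mask(c("F46T", "A114G"), sites))
  functional <- rep(TRUE, n)
  functional[nf + 1L] <- FALSE
  lambda[nf + 1L] <- NA_real_
  ls <- landscape(sites, 357, lambda = lambda, functional = functional)

  newick <- paste0(
    "((((((((((Human,Chimpanzee),Gorilla),Orangutan),Gibbon),Macaque),",
    "(Marmoset,SquirrelMonkey)),Tarsier),AyeAye),",
    "(((Mouse,Rat),Squirrel),GuineaPig)),Elephant);")
  tree <- ape::read.tree(text = newick)

  taxa <- c("Human", "Chimpanzee", "Gorilla", "Orangutan", "Gibbon",
            "Macaque", "Marmoset", "SquirrelMonkey", "Tarsier", "AyeAye",
            "Mouse", "Rat", "Squirrel", "GuineaPig", "Elephant")
  anc <- c(F46T = "F", F49L = "F", T52F = "T", F86L = "F", T93P = "T",
           A114G = "A", S118T = "S")
  der <- c(F46T = "T", F49L = "L", T52F = "F", F86L = "L", T93P = "P",
           A114G = "G", S118T = "T")
  chars <- matrix(rep(anc, each = length(taxa)), length(taxa), 7L,
                  dimnames = list(taxa, sites))
  derived_in <- list(
    T93P = taxa[1:9], A114G = taxa[1:9],           # + Tarsier
    F86L = taxa[1:8],                              # anthropoids
    F49L = taxa[1:6], S118T = taxa[1:6],           # catarrhines
    F46T = taxa[1:5], T52F = taxa[1:5]             # apes
  )
  for (s in names(derived_in)) chars[derived_in[[s]], s] <- der[[s]]

  ages <- data.frame(
    node = c("root", "boreoeutheria", "primates", "haplorhini",
             "anthropoidea", "catarrhini", "hominoidea"),
    age_my = c(105, 90, 80, 75, 45, 30, 20)
  )

  list(
    landscape = ls,
    truth = list(theta = theta, nonfunctional = sort(as.integer(nf))),
    partial_order = list(c("T93P", "A114G"), "F86L", c("F49L", "S118T"),
                         c("F46T", "T52F")),
    tree = tree, characters = chars, ages = ages, focal_tip = "Human"
  )
}
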