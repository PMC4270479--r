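# Bitmask arithmetic on the subset lattice of L biallelic sites.
# Site j (1-based) occupies bit j-1; the ancestral genotype is mask 0L.
# All masks are plain R integers, so L is capped at 20 well below the
# 31-bit limit (the cap is enforced where landscapes are built).

#' Number of set bits in each mask
#'
#' The mutational order of a genotype: how many of the L sites carry the
#' derived state.
#'
#' @param x integer vector of genotype bitmasks.
#' @return integer vector of bit counts.
#' @keywords internal
popcount <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + x %% 2L
    x <- x %/% 2L
  }
  n
}

#' All submasks of a mask (including 0 and the mask itself)
#' @keywords internal
#' @noRd
submasks <- function(mask) {
  mask <- as.integer(mask)
  out <- integer(2L^popcount(mask))
  i <- 1L
  sub <- mask
  repeat {
    out[i] <- sub
    if (sub == 0L) break
    sub <- bitwAnd(sub - 1L, mask)
    i <- i + 1L
  }
  out
}

# mask for a set of 1-based site indices
bit_mask <- function(idx) {
  if (length(idx) == 0L) return(0L)
  as.integer(sum(bitwShiftL(1L, as.integer(idx) - 1L)))
}

# 1-based site indices present in a mask
mask_sites <- function(mask) {
  mask <- as.integer(mask)
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(31L) - 1L)) != 0L)
}

# masks 0..2^L-1 ordered by subset size, ties broken by mask value; this
# is the ordering under which the incidence matrix is unit lower-triangular
lattice_order <- function(L) {
  masks <- 0:(2L^L - 1L)
  masks[order(popcount(masks), masks)]
}

#' Resolve a genotype specification to a bitmask
#'
#' Accepts an integer mask, a character vector of mutation labels, or a
#' single "+"-joined label string ("ancestor" denotes the empty set).
#'
#' @param g genotype: mask, label vector, or joined label string.
#' @param sites ordered character vector of the L site labels.
#' @return integer bitmask.
#' @keywords internal
genotype_mask <- function(g, sites) {
  if (is.numeric(g)) {
    m <- as.integer(g)
    if (length(m) != 1L || is.na(m) || m < 0L || m >= 2L^length(sites))
      stop("genotype mask out of range for ", length(sites), " sites")
    return(m)
  }
  g <- as.character(g)
  if (length(g) == 1L && (g == "ancestor" || g == ""))
    return(0L)
  if (length(g) == 1L && grepl("+", g, fixed = TRUE))
    g <- strsplit(g, "+", fixed = TRUE)[[1L]]
  idx <- match(g, sites)
  if (anyNA(idx))
    stop("unknown mutation label(s): ", paste(g[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx))
    stop("duplicated mutation label in genotype: ", paste(g, collapse = "+"))
  bit_mask(idx)
}

# canonical label for a mask: "+"-joined site labels, "ancestor" for 0
mask_label <- function(mask, sites) {
  vapply(as.integer(mask), function(m) {
    if (m == 0L) "ancestor" else paste(sites[mask_sites(m)], collapse = "+")
  }, character(1L))
}
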