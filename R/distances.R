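# Molecular distances between sequences/haplotypes.

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) log(1 - 4p/3)`, the expected number of substitutions per site
#' correcting the raw p-distance for multiple hits under equal base
#' frequencies and exchange rates. Undefined at `p >= 0.75`.
#'
#' @param p Proportion(s) of differing sites, `0 <= p < 0.75`.
#' @return Corrected distance(s), `d >= p`.
#' @examples
#' jukes_cantor(0.05)  # 0.05174
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75))
    stop("Jukes-Cantor distance undefined for p >= 0.75 (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

# Hamming distance matrix between rows of a character or integer matrix.
# Sites equal in both rows count as matches; everything else differs.
hap_hamming <- function(hm) {
  L <- ncol(hm)
  syms <- unique(as.vector(hm))
  matches <- matrix(0, nrow(hm), nrow(hm))
  for (b in syms) matches <- matches + tcrossprod(hm == b)
  D <- L - matches
  diag(D) <- 0
  D
}

# Squared-distance matrix between haplotypes for AMOVA. Following the
# Arlequin convention, the "squared distance" between two haplotypes is the
# (model-corrected) number of differing sites:
#   raw        - Hamming count
#   jc         - JC per-site distance x number of compared sites
#   haplotype  - 0/1 identity (frequency-based F_ST)
# With pairwise site deletion, sites holding '-'/'N' in either haplotype are
# excluded pair by pair.
hap_sq_dist <- function(hm, model = c("jc", "raw", "haplotype"),
                        pairwise_deletion = FALSE) {
  model <- match.arg(model)
  H <- nrow(hm)
  if (model == "haplotype") {
    D <- matrix(1, H, H); diag(D) <- 0
    return(D)
  }
  if (!pairwise_deletion) {
    ham <- hap_hamming(hm)
    L <- ncol(hm)
    if (model == "raw") return(ham)
    return(jukes_cantor(ham / L) * L)
  }
  good <- hm %in% c(DNA_BASES)
  dim(good) <- dim(hm)
  D <- matrix(0, H, H)
  for (i in seq_len(H - 1L)) {
    for (j in (i + 1L):H) {
      ok <- good[i, ] & good[j, ]
      L_ij <- sum(ok)
      if (L_ij == 0L) stop("haplotype pair with no comparable sites")
      diff <- sum(hm[i, ok] != hm[j, ok])
      D[i, j] <- D[j, i] <- if (model == "raw") diff
                            else jukes_cantor(diff / L_ij) * L_ij
    }
  }
  D
}

#' Pairwise distance matrix between individual sequences
#'
#' @param sets An [aligned_sample_set()] or list of them.
#' @param model `"jc"` (Jukes-Cantor corrected; default), `"raw"`
#'   (p-distance counts), or `"haplotype"` (0/1 identity).
#' @param site_policy `"complete"` (drop columns containing `-`/`N` in the
#'   pooled alignment) or `"pairwise"` (per-pair deletion).
#' @return An object of class `distance_matrix`: list with `ids`, `matrix`
#'   (squared molecular distances, i.e. corrected numbers of differences)
#'   and `metric`.
#' @export
seq_distance_matrix <- function(sets, model = c("jc", "raw", "haplotype"),
                                site_policy = c("complete", "pairwise")) {
  model <- match.arg(model)
  site_policy <- match.arg(site_policy)
  hi <- hap_indices(sets, if (site_policy == "complete") "complete" else "none")
  hm <- do.call(rbind, strsplit(hi$table$haplotypes, "", fixed = TRUE))
  D <- hap_sq_dist(hm, model, pairwise_deletion = site_policy == "pairwise")
  full <- D[hi$idx, hi$idx]
  if (inherits(sets, "aligned_sample_set")) sets <- list(sets)
  ids <- unlist(lapply(sets, `[[`, "ids"), use.names = FALSE)
  dimnames(full) <- list(ids, ids)
  structure(list(ids = ids, matrix = full, metric = model),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix (", x$metric, "): ", length(x$ids), " sequences\n",
      sep = "")
  invisible(x)
}
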