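# Microsatellite genotype screening: probability of identity and duplicate
# detection, used to confirm that biopsy samples represent distinct whales.

#' Construct a multilocus genotype table
#'
#' @param ids Character vector of sample ids.
#' @param alleles Integer matrix with `2 * n_loci` columns (two allele codes
#'   per locus, unordered); `NA` marks a missing genotype (both columns of a
#'   locus must then be `NA`).
#' @param loci Optional locus names (default `L1..Lk`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, alleles, loci = NULL) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) %% 2L != 0L) stop("allele matrix needs 2 columns per locus")
  n_loci <- ncol(alleles) / 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  if (length(ids) != nrow(alleles)) stop("ids and allele rows differ in length")
  for (l in seq_len(n_loci)) {
    a <- alleles[, 2L * l - 1L]; b <- alleles[, 2L * l]
    if (any(is.na(a) != is.na(b)))
      stop("locus ", loci[l], ": a non-missing genotype needs exactly 2 alleles")
  }
  structure(list(ids = as.character(ids), alleles = alleles,
                 loci = loci, n_loci = n_loci),
            class = "genotype_table")
}

#' Read genotypes from TSV
#'
#' Expected layout: `sample_id`, then two columns per locus
#' (`locus1_a`, `locus1_b`, ...). Missing genotypes may be blank or `NA`.
#'
#' @param path Path to the TSV file.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  al <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(al) <- "integer"
  loci <- unique(sub("_[ab]$", "", colnames(d)[-1L]))
  genotype_table(ids, al, loci = loci)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", length(x$ids), " samples x ", x$n_loci, " loci\n",
      sep = "")
  invisible(x)
}

#' Probability of identity from multilocus genotypes
#'
#' Computes the per-locus probability that two unrelated individuals drawn
#' from a randomly mating population share a genotype
#' (`PID_HW = sum(p^4) + sum_{i<j} (2 p_i p_j)^2`) and the conservative
#' full-sibling version
#' (`PID_sib = 0.25 + 0.5 sum(p^2) + 0.5 (sum(p^2))^2 - 0.25 sum(p^4)`),
#' multiplied across loci. Allele frequencies are taken from the data.
#'
#' @param g A [genotype_table()].
#' @return A list with `pid_hw`, `pid_sib` (products over loci) and
#'   `per_locus` (data.frame of per-locus values).
#' @examples
#' g <- genotype_table(c("a", "b"), rbind(c(1L, 2L), c(1L, 1L)))
#' probability_of_identity(g)
#' @export
probability_of_identity <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  hw <- sib <- numeric(0)
  used <- character(0)
  for (l in seq_len(g$n_loci)) {
    al <- c(g$alleles[, 2L * l - 1L], g$alleles[, 2L * l])
    al <- al[!is.na(al)]
    if (length(al) == 0L) {
      warning("locus ", g$loci[l], " has no observations; excluded")
      next
    }
    p <- as.numeric(table(al)) / length(al)
    s2 <- sum(p^2); s4 <- sum(p^4)
    hw <- c(hw, 2 * s2^2 - s4)          # = sum p^4 + sum_{i<j} (2 p_i p_j)^2
    sib <- c(sib, 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4)
    used <- c(used, g$loci[l])
  }
  if (length(hw) == 0L) stop("no locus with any observed genotype")
  list(pid_hw = prod(hw), pid_sib = prod(sib),
       per_locus = data.frame(locus = used, pid_hw = hw, pid_sib = sib))
}

#' Find duplicate individuals by genotype matching
#'
#' Reports pairs of samples matching at every compared locus (exact
#' recaptures) and pairs mismatching at no more than `mismatch_tolerance`
#' loci (candidate recaptures hidden by genotyping error). Loci missing in
#' either member of a pair are skipped for that pair.
#'
#' @param g A [genotype_table()].
#' @param mismatch_tolerance 0, 1 or 2 mismatching loci for the flagged set.
#' @return A data.frame with columns `id_a`, `id_b`, `n_compared`,
#'   `n_mismatch`, `exact`.
#' @export
find_duplicates <- function(g, mismatch_tolerance = 2L) {
  stopifnot(inherits(g, "genotype_table"))
  if (!mismatch_tolerance %in% 0:2) stop("mismatch_tolerance must be 0, 1 or 2")
  n <- length(g$ids)
  # canonical per-locus genotype key (sorted allele pair)
  keys <- matrix("", n, g$n_loci)
  for (l in seq_len(g$n_loci)) {
    a <- g$alleles[, 2L * l - 1L]; b <- g$alleles[, 2L * l]
    keys[, l] <- ifelse(is.na(a), NA_character_,
                        paste(pmin(a, b), pmax(a, b), sep = "/"))
  }
  out <- data.frame(id_a = character(0), id_b = character(0),
                    n_compared = integer(0), n_mismatch = integer(0),
                    exact = logical(0))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(keys[i, ]) & !is.na(keys[j, ])
      nc <- sum(ok)
      if (nc == 0L) next
      mm <- sum(keys[i, ok] != keys[j, ok])
      if (mm <= mismatch_tolerance) {
        out <- rbind(out, data.frame(id_a = g$ids[i], id_b = g$ids[j],
                                     n_compared = nc, n_mismatch = mm,
                                     exact = mm == 0L))
      }
    }
  }
  out
}
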