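# Haplotype collapsing and bookkeeping.

# Retained-site mask over a pooled character matrix. "complete" drops every
# column containing '-' or 'N' anywhere in the pool (DnaSP-style complete
# deletion), so S and H are computed on a single fixed site set; "none"
# retains all columns.
site_mask <- function(pooled, policy = c("complete", "none")) {
  policy <- match.arg(policy)
  if (policy == "none") return(seq_len(ncol(pooled)))
  keep <- which(colSums(pooled == "-" | pooled == "N") == 0L)
  if (length(keep) == 0L) stop("no retained sites: every column contains '-' or 'N'")
  keep
}

#' Collapse aligned sample sets into a haplotype table
#'
#' Distinct sequences over the retained sites become haplotypes; the table
#' records per-population counts, so column sums equal sample-set sizes.
#' Under the default `"complete"` site policy every alignment column holding
#' a gap or `N` anywhere in the pooled data is dropped before collapsing,
#' giving a single fixed site mask shared by all downstream statistics.
#'
#' @param sets A single [aligned_sample_set()] or a list of them sharing an
#'   alignment length.
#' @param site_policy `"complete"` (drop columns with `-`/`N` in the pool;
#'   default) or `"none"` (keep all columns).
#' @return An object of class `haplotype_table`: `haplotypes` (character
#'   vector of collapsed sequences), `counts` (haplotype x set integer
#'   matrix), `site_mask` (retained column indices), `length` (original
#'   alignment length).
#' @examples
#' a <- aligned_sample_set("A", c(s1 = "AAT", s2 = "AAT", s3 = "ACT"))
#' b <- aligned_sample_set("B", c(t1 = "AAT"))
#' collapse_haplotypes(list(a, b))
#' @export
collapse_haplotypes <- function(sets, site_policy = c("complete", "none")) {
  if (inherits(sets, "aligned_sample_set")) sets <- list(sets)
  lens <- vapply(sets, function(s) ncol(s$seqs), integer(1L))
  if (length(unique(lens)) > 1L)
    stop("sample sets differ in alignment length: ",
         paste(unique(lens), collapse = ", "))
  pooled <- do.call(rbind, lapply(sets, `[[`, "seqs"))
  mask <- site_mask(pooled, site_policy)
  kept <- pooled[, mask, drop = FALSE]
  keys <- row_keys(kept)
  haps <- unique(keys)
  idx <- match(keys, haps)
  set_ids <- make.unique(vapply(sets, `[[`, character(1L), "set_id"))
  pop <- rep(set_ids, vapply(sets, n_samples, integer(1L)))
  counts <- matrix(0L, nrow = length(haps), ncol = length(sets),
                   dimnames = list(NULL, set_ids))
  tab <- table(idx, factor(pop, levels = set_ids))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  structure(list(haplotypes = haps, counts = counts, site_mask = mask,
                 length = lens[1L]),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table: ", length(x$haplotypes), " haplotypes over ",
      length(x$site_mask), " retained sites (of ", x$length, ") in ",
      ncol(x$counts), " sample set(s)\n", sep = "")
  invisible(x)
}

#' Private haplotypes of one sample set
#'
#' Counts haplotypes whose occurrences are confined to a single population
#' (column `U` of a Table-1 style diversity summary).
#'
#' @param table A [collapse_haplotypes()] result.
#' @param set_id Which population column to assess.
#' @return Integer count of private haplotypes.
#' @export
private_haplotypes <- function(table, set_id) {
  if (!set_id %in% colnames(table$counts))
    stop("unknown sample set '", set_id, "'; table has: ",
         paste(colnames(table$counts), collapse = ", "))
  if (ncol(table$counts) == 1L) {
    warning("single-set table: every observed haplotype is trivially private")
    return(sum(table$counts[, 1L] > 0L))
  }
  here <- table$counts[, set_id] > 0L
  elsewhere <- rowSums(table$counts[, colnames(table$counts) != set_id,
                                    drop = FALSE]) > 0L
  sum(here & !elsewhere)
}

# Haplotype index per individual for one or more sets on a shared mask;
# internal fast path used by permutation tests and the simulator.
hap_indices <- function(sets, site_policy = "complete") {
  tab <- collapse_haplotypes(sets, site_policy)
  if (inherits(sets, "aligned_sample_set")) sets <- list(sets)
  pooled <- do.call(rbind, lapply(sets, `[[`, "seqs"))
  kept <- pooled[, tab$site_mask, drop = FALSE]
  idx <- match(row_keys(kept), tab$haplotypes)
  sizes <- vapply(sets, n_samples, integer(1L))
  list(table = tab, idx = idx,
       pop = rep(seq_along(sets), sizes), sizes = sizes)
}
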