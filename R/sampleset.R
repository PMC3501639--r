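#' Construct an aligned sample set
#'
#' An `aligned_sample_set` is the unit of all statistics in the package: a
#' labelled set of equal-length aligned mtDNA sequences with a sampling age
#' (years before present) attached to every sample. Modern biopsy sets have
#' age 0; ancient sets (archaeological baleen/bone) carry positive ages.
#'
#' @param set_id Short population label, e.g. `"PRI"`, `"HBFB"`, `"BCB"`.
#' @param seqs Either a named character vector of sequence strings or a
#'   character matrix (rows = samples, columns = alignment sites). Characters
#'   must be in `A,C,G,T,-,N` after uppercasing (see `strict`).
#' @param ages Sampling age in years before present: a scalar applied to all
#'   samples, or a named numeric vector keyed by sample id.
#' @param group Optional higher-level label (e.g. `"Atlantic"`, `"Pacific"`).
#' @param strict If `TRUE` (default), IUPAC ambiguity codes other than `N`
#'   are an error; if `FALSE` they are mapped to `N`.
#' @return An object of class `aligned_sample_set` with elements `set_id`,
#'   `ids`, `seqs` (character matrix), `ages`, `group`.
#' @examples
#' s <- aligned_sample_set("toy", c(a = "ACGT", b = "ACGA", c = "ACGT"))
#' s
#' @export
aligned_sample_set <- function(set_id, seqs, ages = 0, group = NA_character_,
                               strict = TRUE) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0(set_id, "_", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != lens[1L]][1L]
      stop("ragged alignment in set '", set_id, "': record '", bad,
           "' has length ", nchar(seqs[bad]), ", expected ", lens[1L])
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  } else if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) rownames(m) <- paste0(set_id, "_", seq_len(nrow(m)))
  } else stop("seqs must be a character vector or matrix")
  if (nrow(m) == 0L) stop("empty sample set '", set_id, "'")
  m[] <- toupper(m)

  ok <- m %in% c(DNA_BASES, "-", "N")
  if (!all(ok)) {
    offending <- unique(m[!ok])
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?", ".")
    if (strict || !all(offending %in% iupac)) {
      rec <- rownames(m)[which(!matrix(ok, nrow(m)), arr.ind = TRUE)[1L, 1L]]
      stop("invalid characters (", paste(offending, collapse = ","),
           ") in record '", rec, "' of set '", set_id,
           "'; use strict = FALSE to map IUPAC ambiguity codes to N")
    }
    m[!ok] <- "N"
  }

  ids <- rownames(m)
  if (anyDuplicated(ids)) stop("duplicate sample ids in set '", set_id, "'")
  if (length(ages) == 1L && is.null(names(ages))) {
    ages <- rep(as.numeric(ages), nrow(m))
  } else {
    if (is.null(names(ages))) stop("per-sample ages must be named by sample id")
    missing <- setdiff(ids, names(ages))
    if (length(missing)) stop("no age given for sample(s): ",
                              paste(head(missing, 3L), collapse = ", "))
    ages <- as.numeric(ages[ids])
  }
  if (any(ages < 0)) stop("sampling ages must be >= 0")
  names(ages) <- ids

  structure(list(set_id = set_id, ids = ids, seqs = m, ages = ages,
                 group = group),
            class = "aligned_sample_set")
}

#' @export
print.aligned_sample_set <- function(x, ...) {
  cat("Aligned sample set '", x$set_id, "': ", length(x$ids), " sequences x ",
      ncol(x$seqs), " bp", sep = "")
  if (!is.na(x$group)) cat(" (group ", x$group, ")", sep = "")
  rng <- range(x$ages)
  if (rng[2] > 0) cat("; ages ", rng[1], "-", rng[2], " ybp", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of samples in a set
#' @param x An `aligned_sample_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) length(x$ids)

#' Read an aligned FASTA file into a sample set
#'
#' Reads a standard (wrapped or single-line) FASTA alignment and attaches a
#' population label and sampling ages. The alignment must be strictly
#' rectangular; a ragged record is a hard error naming the offender.
#'
#' @param path Path to a FASTA file.
#' @param set_id Population label for the whole file.
#' @param ages Scalar age (years before present) or named vector per sample;
#'   see [read_ages()] for the two-column TSV convention.
#' @inheritParams aligned_sample_set
#' @return An [aligned_sample_set()].
#' @export
read_fasta_set <- function(path, set_id, ages = 0, group = NA_character_,
                           strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  chr <- lapply(as.character(dna), toupper)
  lens <- lengths(chr)
  if (length(unique(lens)) > 1L) {
    bad <- names(chr)[lens != lens[1L]][1L]
    stop("ragged alignment in ", path, ": record '", bad, "' has length ",
         lens[[bad]], ", expected ", lens[1L])
  }
  m <- do.call(rbind, chr)
  aligned_sample_set(set_id, m, ages = ages, group = group, strict = strict)
}

#' Read per-sample ages from a two-column TSV
#'
#' @param path TSV with columns `sample_id` and `age_years` (header optional).
#' @return Named numeric vector of ages keyed by sample id.
#' @export
read_ages <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("sample", first, ignore.case = TRUE)
  d <- if (header) {
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    read.table(path, sep = "\t", header = FALSE,
               col.names = c("sample_id", "age_years"),
               stringsAsFactors = FALSE)
  }
  ages <- as.numeric(d[[2L]])
  names(ages) <- as.character(d[[1L]])
  if (any(is.na(ages))) stop("non-numeric ages in ", path)
  ages
}

#' Write sample sets as FASTA files
#'
#' @param sets A list of [aligned_sample_set()] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (one per set, named `<set_id>.fa`).
#' @export
write_sets_fasta <- function(sets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sets, function(s) {
    p <- file.path(dir, paste0(s$set_id, ".fa"))
    dna <- ape::as.DNAbin(tolower(s$seqs))
    ape::write.FASTA(dna, p)
    p
  }, character(1L))
  invisible(paths)
}
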