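#' @importFrom stats aggregate model.frame model.matrix model.response
#'   rpois runif setNames terms delete.response
#' @importFrom graphics hist abline
#' @importFrom utils read.delim write.table head
NULL

# Canonical allele-label grammar: <locality>_<F|M>_<sample>_<a|b|ab>.
# Field labels as printed in range-wide surveys ("3-male 1" style) are mapped
# to this ASCII form upstream or via a custom `label_parser`.
.default_label_regex <- "^([0-9]+)_([FM])_([0-9]+)_(a|b|ab)$"

#' Parse an allele label
#'
#' Decomposes a FASTA header into locality, sex, sample number and allele tag
#' under the canonical grammar `<locality>_<F|M>_<sample>_<a|b|ab>`, e.g.
#' `"23_M_1_a"` for the first allele of male 1 from locality 23. Homozygotes
#' carry the tag `"ab"`: a single record stands for both allele copies.
#'
#' @param label character vector of headers.
#' @param label_parser optional function taking one header and returning a
#'   list with elements `locality` (integer), `sex` (`"F"` or `"M"`),
#'   `sample_no` (integer), `allele_tag` (`"a"`, `"b"` or `"ab"`), or `NULL`
#'   if the header does not parse. Use this hook to adapt other header
#'   dialects to the canonical grammar.
#' @return a data.frame with columns `label`, `locality`, `sex`, `sample_no`,
#'   `allele_tag`, `individual` (the `locality_sex_sample` key).
#' @export
parse_allele_labels <- function(label, label_parser = NULL) {
  stopifnot(is.character(label))
  if (is.null(label_parser)) {
    m <- regmatches(label, regexec(.default_label_regex, label))
    bad <- vapply(m, length, 1L) != 5L
    if (any(bad)) {
      stop("unparseable allele header(s): ",
           paste(utils::head(label[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(
      label      = label,
      locality   = as.integer(vapply(m, `[`, "", 2L)),
      sex        = vapply(m, `[`, "", 3L),
      sample_no  = as.integer(vapply(m, `[`, "", 4L)),
      allele_tag = vapply(m, `[`, "", 5L),
      stringsAsFactors = FALSE
    )
  } else {
    parsed <- lapply(label, label_parser)
    bad <- vapply(parsed, is.null, TRUE)
    if (any(bad)) {
      stop("unparseable allele header(s): ",
           paste(utils::head(label[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(
      label      = label,
      locality   = as.integer(vapply(parsed, function(p) p$locality, 1)),
      sex        = vapply(parsed, function(p) as.character(p$sex), ""),
      sample_no  = as.integer(vapply(parsed, function(p) p$sample_no, 1)),
      allele_tag = vapply(parsed, function(p) as.character(p$allele_tag), ""),
      stringsAsFactors = FALSE
    )
  }
  if (!all(out$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M' in allele headers", call. = FALSE)
  }
  if (!all(out$allele_tag %in% c("a", "b", "ab"))) {
    stop("allele tag must be 'a', 'b' or 'ab'", call. = FALSE)
  }
  out$individual <- paste(out$locality, out$sex, out$sample_no, sep = "_")
  out
}

.valid_bases <- c("A", "C", "G", "T", "N", "-")

#' Construct an aligned marker from sequences and labels
#'
#' @param seqs character matrix (alleles x sites, single characters over
#'   `A,C,G,T,N,-`) or character vector of equal-length strings.
#' @param labels character vector of allele headers (see
#'   [parse_allele_labels()]).
#' @param marker marker name.
#' @param label_parser optional custom header parser.
#' @return an object of class `aligned_marker`: a list with `marker`,
#'   `length`, `seq` (character matrix, rows named by label) and `alleles`
#'   (the parsed label table).
#' @export
aligned_marker <- function(seqs, labels, marker, label_parser = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("ragged alignment: sequence lengths ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  stopifnot(is.matrix(seqs), nrow(seqs) == length(labels))
  seqs <- toupper(seqs)
  if (!all(seqs %in% .valid_bases)) {
    bad <- setdiff(unique(as.vector(seqs)), .valid_bases)
    stop("invalid alignment character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  alleles <- parse_allele_labels(labels, label_parser)
  dup <- duplicated(alleles[, c("individual", "allele_tag")])
  if (any(dup)) {
    stop("duplicate (individual, allele_tag) record(s): ",
         paste(alleles$label[dup], collapse = ", "), call. = FALSE)
  }
  # an "ab" homozygote record excludes separate a/b records for the same
  # individual, and vice versa
  for (ind in unique(alleles$individual)) {
    tags <- alleles$allele_tag[alleles$individual == ind]
    if ("ab" %in% tags && length(tags) > 1L) {
      stop("individual ", ind, " mixes tag 'ab' with other allele records",
           call. = FALSE)
    }
    if (length(tags) > 2L) {
      stop("individual ", ind, " has more than two allele records",
           call. = FALSE)
    }
  }
  rownames(seqs) <- alleles$label
  structure(
    list(marker = marker, length = ncol(seqs), seq = seqs, alleles = alleles),
    class = "aligned_marker"
  )
}

#' Read a marker alignment from a FASTA file
#'
#' Reads a gapped FASTA alignment of phased alleles whose headers follow the
#' label grammar (or a dialect handled by `label_parser`) and validates that
#' all records share one alignment length.
#'
#' @inheritParams aligned_marker
#' @param path path to an aligned FASTA file.
#' @return an `aligned_marker` object.
#' @export
read_alignment <- function(path, marker, label_parser = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ape::as.matrix.DNAbin(dna)))
  seqs[seqs == "?"] <- "N"
  aligned_marker(seqs, names(dna), marker, label_parser)
}

#' Write a marker alignment to FASTA
#'
#' Inverse of [read_alignment()] on canonical records (round-trip identity).
#'
#' @param marker an `aligned_marker`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(marker, path) {
  stopifnot(inherits(marker, "aligned_marker"))
  lines <- character(2L * nrow(marker$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(marker$seq))
  lines[c(FALSE, TRUE)] <- apply(marker$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.aligned_marker <- function(x, ...) {
  n_ind <- length(unique(x$alleles$individual))
  cat("Aligned marker '", x$marker, "': ", nrow(x$seq),
      " allele records (", n_ind, " individuals), ", x$length, " bp\n",
      sep = "")
  invisible(x)
}

#' Read a locality-to-region map
#'
#' @param path TSV with columns `locality`, `region`.
#' @return named character vector mapping locality id to region label.
#' @export
read_region_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locality", "region") %in% names(tab)))
  region_map(tab$locality, tab$region)
}

#' Construct a locality-to-region map
#'
#' @param locality integer locality ids.
#' @param region region label per locality, e.g. `"SE_refugia"`,
#'   `"Pannonian"`, `"NW_Europe"`.
#' @return named character vector (names = locality ids).
#' @export
region_map <- function(locality, region) {
  stopifnot(length(locality) == length(region), !anyDuplicated(locality))
  stats::setNames(as.character(region), as.character(as.integer(locality)))
}

#' Pair alleles into diploid genotypes
#'
#' Assembles one genotype per individual from a marker's allele records. An
#' `"ab"` record expands into a homozygote (both copies identical). An
#' individual with a single `a` or `b` record gets a missing second allele
#' and is flagged; such individuals are excluded from pairwise-distance
#' analyses downstream. For males the two copies are an X and a Y allele
#' (unassigned); for females two X copies.
#'
#' @param marker an `aligned_marker`.
#' @param regions a region map (see [region_map()]); must cover every
#'   locality present in the alignment.
#' @return data.frame of class `genotype_table`: one row per individual with
#'   columns `individual`, `locality`, `sex`, `sample_no`, `region`,
#'   `allele1`, `allele2` (row indices into `marker$seq`; `allele2` is `NA`
#'   when missing) and `missing_allele` (logical flag).
#' @export
pair_alleles <- function(marker, regions) {
  stopifnot(inherits(marker, "aligned_marker"))
  al <- marker$alleles
  locs <- unique(al$locality)
  unmapped <- setdiff(as.character(locs), names(regions))
  if (length(unmapped)) {
    stop("localities missing from region map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  inds <- unique(al$individual)
  rows <- lapply(inds, function(ind) {
    rec <- which(al$individual == ind)
    tags <- al$allele_tag[rec]
    first <- rec[1L]
    if (identical(tags, "ab")) {
      a1 <- rec; a2 <- rec; miss <- FALSE
    } else if (length(rec) == 2L) {
      ord <- order(tags)  # 'a' before 'b': p_d is tag-order invariant anyway
      a1 <- rec[ord[1L]]; a2 <- rec[ord[2L]]; miss <- FALSE
    } else {
      a1 <- rec; a2 <- NA_integer_; miss <- TRUE
    }
    data.frame(
      individual = ind,
      locality   = al$locality[first],
      sex        = al$sex[first],
      sample_no  = al$sample_no[first],
      region     = unname(regions[as.character(al$locality[first])]),
      allele1    = a1,
      allele2    = a2,
      missing_allele = miss,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genotype_table", "data.frame")
  attr(out, "marker") <- marker$marker
  out
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable if it carries at least two distinct states; it is
#' parsimony-informative if at least two states each occur in at least two
#' sequences. `N` is treated as missing at a site and never counts as a
#' state. Under the default policy (`gap_as_state = FALSE`, the DnaSP-like
#' convention) any column containing a gap is excluded entirely; with
#' `gap_as_state = TRUE` the gap is counted as a fifth character state.
#'
#' @param marker an `aligned_marker`.
#' @param gap_as_state logical; count `-` as a fifth state instead of
#'   dropping gapped columns.
#' @return named integer vector `c(variable = , parsimony_informative = )`.
#' @export
count_variable_sites <- function(marker, gap_as_state = FALSE) {
  stopifnot(inherits(marker, "aligned_marker"))
  seqs <- marker$seq
  if (nrow(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(seqs))) {
    col <- seqs[, j]
    if (!gap_as_state && any(col == "-")) next
    col <- col[col != "N"]
    if (!gap_as_state) col <- col[col != "-"]
    if (length(col) < 2L) next
    counts <- table(col)
    if (length(counts) >= 2L) {
      variable <- variable + 1L
      if (sum(counts >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  c(variable = variable, parsimony_informative = informative)
}

#' Export a genotype table to TSV
#'
#' @param genotypes a `genotype_table` from [pair_alleles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(as.data.frame(genotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
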