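# Coordinates are 1-based inclusive alignment columns throughout (R idiom).

#' Annotate a microsatellite-like repeat tract
#'
#' Declares a tandem-repeat interval of a marker's alignment. At recoding
#' time each allele's copy number is counted inside the interval (ignoring
#' alignment gaps) and the whole interval is removed from the SNP columns, so
#' that one repeat-copy difference contributes exactly one mutational step.
#'
#' @param marker marker name.
#' @param start,end 1-based inclusive alignment columns.
#' @param motif repeat motif (1-6 bp typically).
#' @return a `repeat_annotation` object.
#' @export
repeat_annotation <- function(marker, start, end, motif) {
  stopifnot(nchar(motif) >= 1L, end > start, start >= 1L)
  structure(list(marker = marker, start = as.integer(start),
                 end = as.integer(end), motif = toupper(motif)),
            class = "repeat_annotation")
}

#' Annotate a large indel
#'
#' Declares a large insertion/deletion interval, recoded as a single binary
#' presence/absence character (one mutational step between states). Gaps
#' shorter than `large_indel_threshold` are left in the SNP columns and
#' counted column-by-column as a fifth state.
#'
#' @param marker marker name.
#' @param start,end 1-based inclusive alignment columns.
#' @param large_indel_threshold minimum span (bp) to qualify as large
#'   (default 10).
#' @return an `indel_annotation` object.
#' @export
indel_annotation <- function(marker, start, end, large_indel_threshold = 10L) {
  stopifnot(start >= 1L, end >= start)
  if (end - start + 1L < large_indel_threshold) {
    stop("indel span ", end - start + 1L, " bp is below the large-indel ",
         "threshold (", large_indel_threshold, " bp); leave it to the SNP ",
         "columns as gap-as-fifth-state", call. = FALSE)
  }
  structure(list(marker = marker, start = as.integer(start),
                 end = as.integer(end)),
            class = "indel_annotation")
}

.count_tandem_copies <- function(degapped, motif) {
  if (!nzchar(degapped)) return(0L)
  runs <- gregexpr(paste0("(?:", motif, ")+"), degapped)[[1L]]
  if (runs[1L] == -1L) return(0L)
  max(attr(runs, "match.length")) %/% nchar(motif)
}

#' Count repeat copy numbers per allele
#'
#' Evaluates repeat annotations against an alignment: for each allele, the
#' number of exact tandem copies of the motif within the annotated interval,
#' alignment gaps ignored, partial copies ignored. Annotations whose motif is
#' found in no allele are dropped with a warning.
#'
#' @param marker an `aligned_marker`.
#' @param annotations a list of [repeat_annotation()] objects (a single
#'   annotation is accepted).
#' @return the annotations, each augmented with an integer `copies` vector
#'   named by allele label.
#' @export
annotate_repeats <- function(marker, annotations) {
  stopifnot(inherits(marker, "aligned_marker"))
  if (inherits(annotations, "repeat_annotation")) annotations <- list(annotations)
  kept <- list()
  for (ann in annotations) {
    if (ann$end > marker$length) {
      stop("repeat interval [", ann$start, ", ", ann$end,
           "] out of range for ", marker$length, " bp alignment",
           call. = FALSE)
    }
    win <- marker$seq[, ann$start:ann$end, drop = FALSE]
    degapped <- apply(win, 1L, function(r) paste(r[r != "-"], collapse = ""))
    copies <- vapply(degapped, .count_tandem_copies, 0L, motif = ann$motif)
    if (all(copies == 0L)) {
      warning("motif ", ann$motif, " not found in any allele over [",
              ann$start, ", ", ann$end, "]; annotation dropped",
              call. = FALSE)
      next
    }
    ann$copies <- copies
    kept[[length(kept) + 1L]] <- ann
  }
  kept
}

#' Auto-detect tandem repeat tracts
#'
#' Scans every allele for runs of at least `min_copies` exact tandem copies
#' of any motif of the given lengths, merges overlapping hits, and returns
#' one annotation per detected tract (copy numbers counted as in
#' [annotate_repeats()]). Short runs below `min_span` alignment columns are
#' ignored to avoid flagging trivial homopolymer triplets.
#'
#' @param marker an `aligned_marker`.
#' @param min_copies minimum tandem copies to report (default 3).
#' @param motif_lengths candidate motif lengths in bp (default 1:6).
#' @param min_span minimum run length in bp (default 6).
#' @return list of annotated `repeat_annotation` objects (possibly empty).
#' @export
detect_repeats <- function(marker, min_copies = 3L, motif_lengths = 1:6,
                           min_span = 6L) {
  stopifnot(inherits(marker, "aligned_marker"))
  hits <- list()
  for (i in seq_len(nrow(marker$seq))) {
    s <- paste(marker$seq[i, ], collapse = "")
    for (k in motif_lengths) {
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_copies - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      for (h in seq_along(m)) {
        if (len[h] < min_span) next
        motif <- substr(s, m[h], m[h] + k - 1L)
        # skip runs that are also pure homopolymers of a shorter period
        if (k > 1L && length(unique(strsplit(motif, "")[[1L]])) == 1L) next
        hits[[length(hits) + 1L]] <- list(start = m[h],
                                          end = m[h] + len[h] - 1L,
                                          motif = motif,
                                          span = len[h])
      }
    }
  }
  if (!length(hits)) return(list())
  # merge overlapping hits, preferring the longest span's motif
  hits <- hits[order(vapply(hits, `[[`, 1, "span"), decreasing = TRUE)]
  merged <- list()
  for (h in hits) {
    ov <- FALSE
    for (j in seq_along(merged)) {
      if (h$start <= merged[[j]]$end && h$end >= merged[[j]]$start) {
        merged[[j]]$start <- min(merged[[j]]$start, h$start)
        merged[[j]]$end <- max(merged[[j]]$end, h$end)
        ov <- TRUE
        break
      }
    }
    if (!ov) merged[[length(merged) + 1L]] <- h
  }
  anns <- lapply(merged, function(h)
    repeat_annotation(marker$marker, h$start, h$end, h$motif))
  annotate_repeats(marker, anns)
}

.intervals_of <- function(annotations) {
  if (!length(annotations)) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = vapply(annotations, `[[`, 1L, "start"),
             end = vapply(annotations, `[[`, 1L, "end"))
}

#' Recode an alignment into mutational-step characters
#'
#' Splits a marker's alignment into three character blocks sharing one
#' schema across alleles: SNP columns (annotated intervals removed; gaps kept
#' as a fifth state), one integer copy-number character per repeat tract, and
#' one binary presence/absence character per large indel. The step distance
#' between two recoded alleles is then the number of differing SNP columns
#' plus the absolute copy-number differences plus the number of differing
#' indel states.
#'
#' @param marker an `aligned_marker`.
#' @param repeats list of repeat annotations (from [annotate_repeats()] or
#'   [detect_repeats()]); may be empty.
#' @param indels list of [indel_annotation()] objects; may be empty. An
#'   allele is scored `absent` for an indel when more than half of the
#'   interval is gap characters.
#' @return a `recoded_alignment`: list with `marker`, `snp` (character
#'   matrix), `repeats` (integer matrix, one column per tract), `indels`
#'   (0/1 matrix), `alleles` (label table), `schema` (annotation intervals).
#' @export
recode_alignment <- function(marker, repeats = list(), indels = list()) {
  if (inherits(marker, "recoded_alignment")) {
    stop("input is already recoded; recoding is not re-applied",
         call. = FALSE)
  }
  stopifnot(inherits(marker, "aligned_marker"))
  if (inherits(repeats, "repeat_annotation")) repeats <- list(repeats)
  if (inherits(indels, "indel_annotation")) indels <- list(indels)
  if (length(repeats) && is.null(repeats[[1L]]$copies)) {
    repeats <- annotate_repeats(marker, repeats)
  }
  iv <- rbind(.intervals_of(repeats), .intervals_of(indels))
  if (nrow(iv) > 1L) {
    iv_s <- iv[order(iv$start), ]
    if (any(iv_s$start[-1L] <= iv_s$end[-nrow(iv_s)])) {
      stop("overlapping annotations", call. = FALSE)
    }
  }
  if (nrow(iv) && max(iv$end) > marker$length) {
    stop("annotation interval out of range", call. = FALSE)
  }
  masked <- rep(FALSE, marker$length)
  for (k in seq_len(nrow(iv))) masked[iv$start[k]:iv$end[k]] <- TRUE
  snp <- marker$seq[, !masked, drop = FALSE]

  rep_mat <- matrix(integer(), nrow = nrow(marker$seq), ncol = 0L)
  if (length(repeats)) {
    rep_mat <- vapply(repeats, function(a) as.integer(a$copies),
                      integer(nrow(marker$seq)))
    if (is.null(dim(rep_mat))) rep_mat <- matrix(rep_mat, nrow = 1L)
    colnames(rep_mat) <- vapply(repeats, function(a)
      paste0(a$motif, "_", a$start), "")
  }
  ind_mat <- matrix(integer(), nrow = nrow(marker$seq), ncol = 0L)
  if (length(indels)) {
    ind_mat <- vapply(indels, function(a) {
      win <- marker$seq[, a$start:a$end, drop = FALSE]
      gap_frac <- rowMeans(win == "-")
      as.integer(gap_frac <= 0.5)  # 1 = sequence present
    }, integer(nrow(marker$seq)))
    if (is.null(dim(ind_mat))) ind_mat <- matrix(ind_mat, nrow = 1L)
    colnames(ind_mat) <- vapply(indels, function(a)
      paste0("indel_", a$start, "_", a$end), "")
  }
  rownames(rep_mat) <- rownames(ind_mat) <- rownames(marker$seq)
  structure(
    list(marker = marker$marker, snp = snp, repeats = rep_mat,
         indels = ind_mat, alleles = marker$alleles,
         schema = list(length = marker$length, masked = which(masked),
                       n_snp = ncol(snp), n_rep = ncol(rep_mat),
                       n_indel = ncol(ind_mat))),
    class = "recoded_alignment"
  )
}

#' @export
print.recoded_alignment <- function(x, ...) {
  cat("Recoded marker '", x$marker, "': ", nrow(x$snp), " alleles; ",
      x$schema$n_snp, " SNP columns, ", x$schema$n_rep,
      " repeat character(s), ", x$schema$n_indel, " indel character(s)\n",
      sep = "")
  invisible(x)
}

#' Extract one allele's recoded character vector
#'
#' @param recoded a `recoded_alignment`.
#' @param i allele row index or label.
#' @return a `recoded_allele`: list with `snp`, `repeats`, `indels`.
#' @export
recoded_allele <- function(recoded, i) {
  stopifnot(inherits(recoded, "recoded_alignment"))
  structure(list(snp = recoded$snp[i, ],
                 repeats = recoded$repeats[i, ],
                 indels = recoded$indels[i, ]),
            class = "recoded_allele")
}

#' Mutational-step distance between two recoded alleles
#'
#' Counts differing SNP columns (gap `-` is a fifth state; sites with `N` in
#' either allele are skipped), plus the sum of absolute repeat copy-number
#' differences, plus the number of differing indel states. A metric on
#' recoded vectors.
#'
#' @param a,b `recoded_allele` objects (or plain lists with `snp`,
#'   `repeats`, `indels` elements) sharing one schema.
#' @return non-negative integer step count.
#' @export
step_distance <- function(a, b) {
  if (length(a$snp) != length(b$snp) ||
      length(a$repeats) != length(b$repeats) ||
      length(a$indels) != length(b$indels)) {
    stop("schema mismatch between recoded alleles", call. = FALSE)
  }
  ok <- a$snp != "N" & b$snp != "N"
  d_snp <- sum(a$snp[ok] != b$snp[ok])
  d_rep <- if (length(a$repeats)) sum(abs(a$repeats - b$repeats)) else 0L
  d_ind <- if (length(a$indels)) sum(a$indels != b$indels) else 0L
  as.integer(d_snp + d_rep + d_ind)
}

#' All pairwise step distances between alleles
#'
#' @param recoded a `recoded_alignment`.
#' @return symmetric integer matrix of step distances, dimnames = allele
#'   labels.
#' @export
pairwise_steps <- function(recoded) {
  stopifnot(inherits(recoded, "recoded_alignment"))
  n <- nrow(recoded$snp)
  snp <- recoded$snp
  d <- matrix(0L, n, n, dimnames = list(rownames(snp), rownames(snp)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- snp[i, ] != "N" & snp[j, ] != "N"
      s <- sum(snp[i, ok] != snp[j, ok])
      if (ncol(recoded$repeats)) {
        s <- s + sum(abs(recoded$repeats[i, ] - recoded$repeats[j, ]))
      }
      if (ncol(recoded$indels)) {
        s <- s + sum(recoded$indels[i, ] != recoded$indels[j, ])
      }
      d[i, j] <- d[j, i] <- as.integer(s)
    }
  }
  d
}

#' Export a recoded character matrix as TSV
#'
#' @param recoded a `recoded_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recoded <- function(recoded, path) {
  stopifnot(inherits(recoded, "recoded_alignment"))
  tab <- data.frame(label = rownames(recoded$snp),
                    snp = apply(recoded$snp, 1L, paste, collapse = ""),
                    stringsAsFactors = FALSE)
  if (ncol(recoded$repeats)) tab <- cbind(tab, recoded$repeats)
  if (ncol(recoded$indels)) tab <- cbind(tab, recoded$indels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
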