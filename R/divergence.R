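#' Within-individual pairwise nucleotide differences
#'
#' For each individual with both alleles present, counts the nucleotide
#' sites differing between its two allele sequences: the X-Y difference in
#' males (whose two copies necessarily comprise an X and a Y), the X-X
#' difference in females. Computed on the raw nucleotide alignment, never on
#' recoded steps. Individuals flagged with a missing allele are excluded
#' (they yield no record); homozygote (`"ab"`) records give `p_d = 0`.
#'
#' Site handling:
#' \describe{
#'   \item{`"pairwise"`}{(default) a site is skipped when either of the two
#'     alleles carries a gap or `N` there;}
#'   \item{`"complete"`}{a site is skipped when any allele of the whole
#'     marker carries a gap or `N` there (classic complete-deletion).}
#' }
#'
#' @param marker an `aligned_marker`.
#' @param genotypes a `genotype_table` from [pair_alleles()].
#' @param policy `"pairwise"` or `"complete"`.
#' @return data.frame of class `pd_table`: one row per retained individual
#'   with `individual`, `sex`, `region`, `marker`, `pd` (integer count) and
#'   `sites_used`.
#' @export
within_individual_pd <- function(marker, genotypes,
                                 policy = c("pairwise", "complete")) {
  stopifnot(inherits(marker, "aligned_marker"),
            inherits(genotypes, "genotype_table"))
  policy <- match.arg(policy)
  g <- as.data.frame(genotypes)
  seqs <- marker$seq
  global_ok <- rep(TRUE, ncol(seqs))
  if (policy == "complete") {
    global_ok <- colSums(seqs == "-" | seqs == "N") == 0L
  }
  g2 <- g[!g$missing_allele, , drop = FALSE]
  if (!nrow(g2)) stop("no individuals with both alleles present",
                      call. = FALSE)
  pd <- integer(nrow(g2))
  used <- integer(nrow(g2))
  for (k in seq_len(nrow(g2))) {
    s1 <- seqs[g2$allele1[k], ]
    s2 <- seqs[g2$allele2[k], ]
    ok <- global_ok
    if (policy == "pairwise") {
      ok <- ok & s1 != "-" & s1 != "N" & s2 != "-" & s2 != "N"
    }
    pd[k] <- sum(s1[ok] != s2[ok])
    used[k] <- sum(ok)
  }
  out <- data.frame(individual = g2$individual, sex = g2$sex,
                    region = g2$region, marker = marker$marker,
                    pd = pd, sites_used = used, stringsAsFactors = FALSE)
  class(out) <- c("pd_table", "data.frame")
  attr(out, "policy") <- policy
  out
}

#' Summarise p_d by groups
#'
#' Group means and sizes of within-individual pairwise differences, e.g. by
#' sex, region, or sex within region. Empty requested groups are omitted
#' with a warning. Means are reported at full precision; round to one
#' decimal for comparison with published tables.
#'
#' @param pd a `pd_table` from [within_individual_pd()] (rows from several
#'   markers may be concatenated with `rbind`).
#' @param by character vector of grouping columns, any of `"sex"`,
#'   `"region"`, `"marker"`.
#' @return data.frame with the grouping columns, `n` and `mean_pd`.
#' @export
summarize_pd <- function(pd, by = c("region", "sex")) {
  stopifnot(is.data.frame(pd), all(by %in% names(pd)))
  if (!nrow(pd)) stop("no p_d records", call. = FALSE)
  f <- lapply(pd[by], factor)
  n <- stats::aggregate(pd$pd, f, length)
  m <- stats::aggregate(pd$pd, f, mean)
  out <- n
  names(out) <- c(by, "n")
  out$mean_pd <- m$x
  out
}

#' Dichotomise regions into expansion vs refugial
#'
#' Maps the three phylogeographic regions onto the two-level factor used in
#' the two-way analysis: the post-glacial expansion area (`NW_Europe`)
#' versus the refugial + Pannonian rest of the range.
#'
#' @param region character vector of region labels.
#' @param nw label of the expansion region (default `"NW_Europe"`).
#' @return factor with levels `c("SE_Pannonian", "NW_Europe")` (non-`nw`
#'   labels pooled).
#' @export
region_dichotomy <- function(region, nw = "NW_Europe") {
  factor(ifelse(region == nw, nw, "SE_Pannonian"),
         levels = c("SE_Pannonian", nw))
}

#' Export p_d records to TSV
#'
#' @param pd a `pd_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pd_table <- function(pd, path) {
  utils::write.table(as.data.frame(pd), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
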