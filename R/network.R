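#' Collapse identical recoded alleles into haplotypes
#'
#' Alleles at step distance 0 share a haplotype. Multiplicity counts allele
#' copies: a homozygote record (tag `"ab"`) counts twice. Individuals
#' flagged with a missing second allele are dropped by default so that the
#' sum of multiplicities equals twice the number of complete individuals;
#' set `include_incomplete = TRUE` to keep their single allele.
#'
#' Haplotype ids `H_1, H_2, ...` are assigned by decreasing multiplicity,
#' ties broken lexicographically by the recoded character string, so labels
#' are deterministic.
#'
#' @param recoded a `recoded_alignment`.
#' @param genotypes optional `genotype_table` from [pair_alleles()]; when
#'   supplied, carriers gain a `region` and the missing-allele exclusion is
#'   applied.
#' @param include_incomplete keep single alleles of individuals whose other
#'   allele is missing (default `FALSE`).
#' @return a `haplotype_set`: list with `haplotypes` (list of id, key,
#'   multiplicity, carriers data.frame), `dist` (step-distance matrix between
#'   haplotypes), `recoded` rows retained.
#' @export
collapse_haplotypes <- function(recoded, genotypes = NULL,
                                include_incomplete = FALSE) {
  stopifnot(inherits(recoded, "recoded_alignment"))
  al <- recoded$alleles
  if (nrow(al) == 0L) stop("empty recoded alignment", call. = FALSE)
  keep <- rep(TRUE, nrow(al))
  region <- rep(NA_character_, nrow(al))
  if (!is.null(genotypes)) {
    g <- as.data.frame(genotypes)
    region <- g$region[match(al$individual, g$individual)]
    if (!include_incomplete) {
      miss <- g$individual[g$missing_allele]
      keep <- !(al$individual %in% miss)
    }
  }
  idx <- which(keep)
  key <- vapply(idx, function(i) {
    paste(c(recoded$snp[i, ], recoded$repeats[i, ], recoded$indels[i, ]),
          collapse = "")
  }, "")
  copies <- ifelse(al$allele_tag[idx] == "ab", 2L, 1L)
  groups <- split(seq_along(idx), key)
  haps <- lapply(names(groups), function(k) {
    rows <- groups[[k]]
    list(key = k,
         rep_row = idx[rows[1L]],
         multiplicity = sum(copies[rows]),
         carriers = data.frame(
           individual = al$individual[idx[rows]],
           sex = al$sex[idx[rows]],
           region = region[idx[rows]],
           allele_tag = al$allele_tag[idx[rows]],
           copies = copies[rows],
           stringsAsFactors = FALSE))
  })
  ord <- order(-vapply(haps, `[[`, 1L, "multiplicity"),
               vapply(haps, `[[`, "", "key"))
  haps <- haps[ord]
  for (h in seq_along(haps)) haps[[h]]$id <- paste0("H_", h)
  rep_rows <- vapply(haps, `[[`, 1L, "rep_row")
  nh <- length(haps)
  d <- matrix(0L, nh, nh)
  for (i in seq_len(max(nh - 1L, 0L))) {
    for (j in (i + 1L):nh) {
      d[i, j] <- d[j, i] <- step_distance(
        recoded_allele(recoded, rep_rows[i]),
        recoded_allele(recoded, rep_rows[j]))
    }
  }
  dimnames(d) <- list(paste0("H_", seq_len(nh)), paste0("H_", seq_len(nh)))
  structure(list(haplotypes = haps, dist = d, marker = recoded$marker),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  mult <- vapply(x$haplotypes, `[[`, 1L, "multiplicity")
  cat("Haplotype set for '", x$marker, "': ", length(x$haplotypes),
      " haplotypes, ", sum(mult), " allele copies\n", sep = "")
  invisible(x)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps at which a connection between two
#' haplotypes is still trusted not to hide superimposed changes, at the
#' given confidence. The probability that `j` mutations scattered uniformly
#' over `m` characters all hit distinct characters (hence are all visible
#' and the observed distance is the true mutation count) is computed by the
#' cumulative recursion `P_1 = 1`, `P_j = P_{j-1} * (m - j + 1) / m`; the
#' limit is the largest `j` with `P_j >= confidence`. As confidence
#' approaches 1 only single-step connections are trusted; the limit is
#' non-decreasing in `m`.
#'
#' @param seq_len number of characters `m` (typically the post-recoding
#'   character count of the marker).
#' @param confidence connection probability (default 0.95).
#' @return integer step limit (>= 1).
#' @export
connection_limit <- function(seq_len, confidence = 0.95) {
  stopifnot(seq_len >= 1, confidence > 0, confidence < 1)
  p <- 1
  j <- 1L
  while (j < seq_len) {
    p_next <- p * (seq_len - j) / seq_len
    if (p_next < confidence) break
    p <- p_next
    j <- j + 1L
  }
  j
}

#' Probability of a non-homoplasious connection at j steps
#'
#' The cumulative probability used by [connection_limit()]: chance that `j`
#' mutations land on `j` distinct characters of `m`.
#'
#' @param j number of steps.
#' @param seq_len number of characters.
#' @return probability in (0, 1].
#' @export
parsimony_probability <- function(j, seq_len) {
  stopifnot(j >= 1, seq_len >= 1)
  if (j > seq_len) return(0)
  prod((seq_len - seq(0L, j - 1L)) / seq_len)
}

#' Build a statistical-parsimony haplotype network
#'
#' Minimum-spanning-network construction with tie retention: haplotype pairs
#' are visited in order of increasing step distance; an edge joins a pair
#' whose endpoints were not yet connected at any strictly smaller distance
#' level, and all ties at a level enter together (reticulations are kept).
#' Pairs farther apart than `limit` never connect, so the network may fall
#' apart into several components.
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param limit connection limit in steps (e.g. from [connection_limit()]).
#' @param infer_intermediates insert unlabelled intermediate nodes on
#'   multi-step edges (one per extra step), emulating unsampled haplotypes
#'   (default `FALSE`).
#' @return a `parsimony_network`: list with `edges` (data.frame from, to,
#'   steps), `haplotypes`, `components` (membership vector), `limit`.
#' @export
build_network <- function(haps, limit, infer_intermediates = FALSE) {
  stopifnot(inherits(haps, "haplotype_set"), limit >= 1)
  d <- haps$dist
  n <- nrow(d)
  ids <- rownames(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  if (n > 1L) {
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    steps <- d[pairs]
    okp <- steps <= limit
    pairs <- pairs[okp, , drop = FALSE]
    steps <- steps[okp]
    for (lev in sort(unique(steps))) {
      at <- which(steps == lev)
      # qualification against connectivity from strictly smaller levels
      add <- at[vapply(at, function(k)
        find(pairs[k, 1L]) != find(pairs[k, 2L]), TRUE)]
      for (k in add) {
        edges <- rbind(edges, data.frame(
          from = ids[pairs[k, 1L]], to = ids[pairs[k, 2L]],
          steps = as.integer(lev), stringsAsFactors = FALSE))
      }
      for (k in add) {
        ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  comp <- as.integer(factor(comp, levels = unique(comp)))
  names(comp) <- ids
  inferred <- NULL
  if (infer_intermediates && nrow(edges)) {
    multi <- edges[edges$steps > 1L, , drop = FALSE]
    if (nrow(multi)) {
      inferred <- do.call(rbind, lapply(seq_len(nrow(multi)), function(k) {
        s <- multi$steps[k]
        data.frame(edge_from = multi$from[k], edge_to = multi$to[k],
                   node = paste0("m_", multi$from[k], "_", multi$to[k],
                                 "_", seq_len(s - 1L)),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(edges = edges, haplotypes = haps$haplotypes,
                 components = comp, limit = as.integer(limit),
                 inferred = inferred, marker = haps$marker),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("Parsimony network for '", x$marker, "': ", length(x$components),
      " haplotypes, ", nrow(x$edges), " edges, ",
      max(x$components), " component(s); connection limit ", x$limit,
      " steps\n", sep = "")
  invisible(x)
}

.node_attributes <- function(net) {
  haps <- net$haplotypes
  data.frame(
    id = vapply(haps, `[[`, "", "id"),
    multiplicity = vapply(haps, `[[`, 1L, "multiplicity"),
    n_male = vapply(haps, function(h)
      sum(h$carriers$copies[h$carriers$sex == "M"]), 1L),
    n_female = vapply(haps, function(h)
      sum(h$carriers$copies[h$carriers$sex == "F"]), 1L),
    region = vapply(haps, function(h) {
      r <- h$carriers$region
      if (all(is.na(r))) return(NA_character_)
      tab <- sort(table(r[!is.na(r)]), decreasing = TRUE)
      names(tab)[1L]
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Convert a parsimony network to an igraph object
#'
#' Nodes carry multiplicity, per-sex allele-copy counts and the majority
#' region of their carriers.
#'
#' @param net a `parsimony_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "parsimony_network"))
  nodes <- .node_attributes(net)
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a parsimony network
#'
#' Writes the edge list as TSV (`from`, `to`, `steps`) or the attributed
#' graph as GML. Reading the edge-list TSV back reproduces the edge set.
#'
#' @param net a `parsimony_network`.
#' @param path output path.
#' @param format `"tsv"` (edge list) or `"gml"` (attributed graph).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "gml")) {
  stopifnot(inherits(net, "parsimony_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "gml")
  }
  invisible(path)
}

#' @export
plot.parsimony_network <- function(x, ...) {
  g <- as_igraph(x)
  mult <- igraph::V(g)$multiplicity
  reg <- igraph::V(g)$region
  pal <- c(SE_refugia = "orange", Pannonian = "mediumpurple",
           NW_Europe = "forestgreen")
  col <- ifelse(is.na(reg) | !(reg %in% names(pal)), "grey70", pal[reg])
  plot(g, vertex.size = 6 + 3 * sqrt(mult), vertex.color = col,
       edge.label = igraph::E(g)$steps, ...)
  invisible(x)
}
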