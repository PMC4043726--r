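# Forward-in-time simulator of a sex-linked marker. Sequences are integer
# backbone vectors (1..4 = A,C,G,T) plus one repeat copy-number character
# and one large-indel presence character per allele; rendering into a gapped
# alignment happens only at sampling time. Small deme sizes keep runs at
# desk scale: the analysis needs the X/Y inheritance mechanics, not exact
# neutral-theory expectations.

#' Simulation parameters for a sex-linked marker
#'
#' Defaults emulate the study conditions of a range-wide survey of a
#' sex-linked marker: three phylogeographic demes — a southeastern refugium,
#' the Pannonian basin founded from it, and a NW-Europe deme founded last
#' through a severe bottleneck — with sample sizes per region and sex
#' matching a marker genotyped in 53 complete individuals.
#'
#' @param marker marker name.
#' @param seq_len backbone length in bp (substitution sites; default 992).
#' @param sub_rate substitutions per site per lineage per generation
#'   (default 1.2e-5, scaled so that desk-scale deme sizes yield realistic
#'   within-region diversity).
#' @param repeat_motif,repeat_copies,repeat_step_rate microsatellite-like
#'   tract: motif (default `"AC"`), ancestral copy number (default 8) and
#'   per-transmission probability of a stepwise +/-1 copy change
#'   (reflecting at 0; default 2e-3).
#' @param indel_rate per-transmission probability of flipping the large
#'   indel's presence state (default 5e-5, i.e. rare).
#' @param indel_size rendered indel length in bp, drawn once per marker
#'   from this range (default `c(30, 60)`).
#' @param male_recomb_prob probability `r` per male meiosis of an X-Y
#'   exchange at a single uniform crossover point; `r = 0` lets X-Y
#'   divergence accumulate, large `r` mixes the gametologs (default 0).
#' @param nw_recomb_prob male recombination probability inside the NW
#'   expansion deme after its founding; `NA` (default) inherits
#'   `male_recomb_prob`. Set to 0 with a positive global rate to emulate
#'   recombination arrest on the expansion front.
#' @param t_burnin generations the refugial deme evolves alone (default 300).
#' @param t_pann_gap generations between the Pannonian founding and the NW
#'   founding (default 100).
#' @param t_split generations since the NW founding — the arrest time of
#'   X-Y recombination in the expansion lineage (default 150).
#' @param deme_females,deme_males deme sizes per sex (default 20 each).
#' @param pann_founders,bottleneck founder individuals for the Pannonian and
#'   NW demes (defaults 10 and 4; at least one of each sex).
#' @param n_sample named list `region -> c(F = , M = )` of individuals to
#'   sample; default `SE_refugia` 9/9, `Pannonian` 8/9, `NW_Europe` 8/10.
#' @param seed integer seed (default 1).
#' @return a validated `sim_params` object.
#' @export
sim_params <- function(marker = "marker1",
                       seq_len = 992L,
                       sub_rate = 1.2e-5,
                       repeat_motif = "AC",
                       repeat_copies = 8L,
                       repeat_step_rate = 2e-3,
                       indel_rate = 5e-5,
                       indel_size = c(30L, 60L),
                       male_recomb_prob = 0,
                       nw_recomb_prob = NA_real_,
                       t_burnin = 300L,
                       t_pann_gap = 100L,
                       t_split = 150L,
                       deme_females = 20L,
                       deme_males = 20L,
                       pann_founders = 10L,
                       bottleneck = 4L,
                       n_sample = list(SE_refugia = c(F = 9L, M = 9L),
                                       Pannonian = c(F = 8L, M = 9L),
                                       NW_Europe = c(F = 8L, M = 10L)),
                       seed = 1L) {
  p <- list(marker = marker, seq_len = as.integer(seq_len),
            sub_rate = sub_rate, repeat_motif = toupper(repeat_motif),
            repeat_copies = as.integer(repeat_copies),
            repeat_step_rate = repeat_step_rate, indel_rate = indel_rate,
            indel_size = as.integer(indel_size),
            male_recomb_prob = male_recomb_prob,
            nw_recomb_prob = nw_recomb_prob,
            t_burnin = as.integer(t_burnin),
            t_pann_gap = as.integer(t_pann_gap),
            t_split = as.integer(t_split),
            deme_females = as.integer(deme_females),
            deme_males = as.integer(deme_males),
            pann_founders = as.integer(pann_founders),
            bottleneck = as.integer(bottleneck),
            n_sample = n_sample, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

#' @rdname sim_params
#' @param p a `sim_params`-like list.
#' @export
validate_sim_params <- function(p) {
  if (p$male_recomb_prob < 0 || p$male_recomb_prob > 0.5) {
    stop("male_recomb_prob must lie in [0, 0.5]", call. = FALSE)
  }
  if (!is.na(p$nw_recomb_prob) &&
      (p$nw_recomb_prob < 0 || p$nw_recomb_prob > 0.5)) {
    stop("nw_recomb_prob must lie in [0, 0.5] or NA", call. = FALSE)
  }
  rates <- c(p$sub_rate, p$repeat_step_rate, p$indel_rate)
  if (any(rates < 0)) stop("mutation rates must be >= 0", call. = FALSE)
  if (p$bottleneck < 1L || p$pann_founders < 1L) {
    stop("founder counts must be >= 1", call. = FALSE)
  }
  if (p$seq_len < 10L) stop("seq_len too short", call. = FALSE)
  if (p$repeat_copies < 0L) stop("repeat_copies must be >= 0", call. = FALSE)
  for (reg in names(p$n_sample)) {
    ns <- p$n_sample[[reg]]
    if (ns[["F"]] > p$deme_females || ns[["M"]] > p$deme_males) {
      stop("sample size exceeds deme size for ", reg, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# deme state: matrices (individuals x backbone) per allele slot, plus
# repeat-copy, indel-state and origin-id vectors per slot
.founder_deme <- function(n_f, n_m, anc, copies) {
  L <- length(anc)
  list(
    Xf1 = matrix(anc, n_f, L, byrow = TRUE),
    Xf2 = matrix(anc, n_f, L, byrow = TRUE),
    Xm  = matrix(anc, n_m, L, byrow = TRUE),
    Ym  = matrix(anc, n_m, L, byrow = TRUE),
    rf1 = rep(copies, n_f), rf2 = rep(copies, n_f),
    rxm = rep(copies, n_m), rym = rep(copies, n_m),
    if1 = rep(1L, n_f), if2 = rep(1L, n_f),
    ixm = rep(1L, n_m), iym = rep(1L, n_m),
    of1 = rep(NA_integer_, n_f), of2 = rep(NA_integer_, n_f),
    oxm = rep(NA_integer_, n_m), oym = rep(NA_integer_, n_m)
  )
}

.mutate_block <- function(M, sub_rate) {
  n_mut <- stats::rpois(1L, nrow(M) * ncol(M) * sub_rate)
  if (n_mut > 0L) {
    rows <- sample.int(nrow(M), n_mut, replace = TRUE)
    cols <- sample.int(ncol(M), n_mut, replace = TRUE)
    shift <- sample.int(3L, n_mut, replace = TRUE)
    M[cbind(rows, cols)] <- (M[cbind(rows, cols)] - 1L + shift) %% 4L + 1L
  }
  M
}

.mutate_repeat <- function(r, rate) {
  hit <- stats::runif(length(r)) < rate
  if (any(hit)) {
    delta <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    r[hit] <- r[hit] + delta
    r[r < 0L] <- 1L  # reflect at zero
  }
  r
}

.mutate_indel <- function(s, rate) {
  hit <- stats::runif(length(s)) < rate
  s[hit] <- 1L - s[hit]
  s
}

# maternal gametes: one of the mother's two X copies, no intra-locus
# crossover (segregation alone mixes the X pool)
.maternal_gametes <- function(d, moms) {
  pick2 <- stats::runif(length(moms)) < 0.5
  G <- d$Xf1[moms, , drop = FALSE]
  r <- d$rf1[moms]; s <- d$if1[moms]; o <- d$of1[moms]
  if (any(pick2)) {
    G[pick2, ] <- d$Xf2[moms[pick2], , drop = FALSE]
    r[pick2] <- d$rf2[moms[pick2]]
    s[pick2] <- d$if2[moms[pick2]]
    o[pick2] <- d$of2[moms[pick2]]
  }
  list(G = G, r = r, s = s, o = o)
}

# paternal gametes from the given slot ("X" for daughters, "Y" for sons);
# with probability r_prob the father's X and Y exchange tails at a uniform
# crossover point before transmission. The repeat tract and the indel are
# anchored at fixed backbone positions and travel with their segment.
.paternal_gametes <- function(d, dads, slot, r_prob, rep_pos, ind_pos) {
  L <- ncol(d$Xm)
  if (slot == "X") {
    G <- d$Xm[dads, , drop = FALSE]
    r <- d$rxm[dads]; s <- d$ixm[dads]; o <- d$oxm[dads]
    A <- d$Xm; B <- d$Ym
    rA <- d$rxm; rB <- d$rym; sA <- d$ixm; sB <- d$iym
  } else {
    G <- d$Ym[dads, , drop = FALSE]
    r <- d$rym[dads]; s <- d$iym[dads]; o <- d$oym[dads]
    A <- d$Ym; B <- d$Xm
    rA <- d$rym; rB <- d$rxm; sA <- d$iym; sB <- d$ixm
  }
  n_events <- 0L
  if (r_prob > 0) {
    rec <- which(stats::runif(length(dads)) < r_prob)
    n_events <- length(rec)
    for (k in rec) {
      f <- dads[k]
      cp <- sample.int(L - 1L, 1L)  # tail (cp+1..L) comes from the homolog
      G[k, (cp + 1L):L] <- B[f, (cp + 1L):L]
      if (rep_pos > cp) r[k] <- rB[f]
      if (ind_pos > cp) s[k] <- sB[f]
      # origin id follows the head segment
    }
  }
  list(G = G, r = r, s = s, o = o, n_events = n_events)
}

.next_generation <- function(d, r_prob, p, rep_pos, ind_pos) {
  n_f <- nrow(d$Xf1); n_m <- nrow(d$Xm)
  moms_d <- sample.int(n_f, n_f, replace = TRUE)
  dads_d <- sample.int(n_m, n_f, replace = TRUE)
  moms_s <- sample.int(n_f, n_m, replace = TRUE)
  dads_s <- sample.int(n_m, n_m, replace = TRUE)
  mg_d <- .maternal_gametes(d, moms_d)
  pg_d <- .paternal_gametes(d, dads_d, "X", r_prob, rep_pos, ind_pos)
  mg_s <- .maternal_gametes(d, moms_s)
  pg_s <- .paternal_gametes(d, dads_s, "Y", r_prob, rep_pos, ind_pos)
  nd <- list(
    Xf1 = .mutate_block(mg_d$G, p$sub_rate),
    Xf2 = .mutate_block(pg_d$G, p$sub_rate),
    Xm  = .mutate_block(mg_s$G, p$sub_rate),
    Ym  = .mutate_block(pg_s$G, p$sub_rate),
    rf1 = .mutate_repeat(mg_d$r, p$repeat_step_rate),
    rf2 = .mutate_repeat(pg_d$r, p$repeat_step_rate),
    rxm = .mutate_repeat(mg_s$r, p$repeat_step_rate),
    rym = .mutate_repeat(pg_s$r, p$repeat_step_rate),
    if1 = .mutate_indel(mg_d$s, p$indel_rate),
    if2 = .mutate_indel(pg_d$s, p$indel_rate),
    ixm = .mutate_indel(mg_s$s, p$indel_rate),
    iym = .mutate_indel(pg_s$s, p$indel_rate),
    of1 = mg_d$o, of2 = pg_d$o, oxm = mg_s$o, oym = pg_s$o
  )
  attr(nd, "rec_events") <- pg_d$n_events + pg_s$n_events
  nd
}

# found a new deme from `founders` individuals of `src` (indices into
# females/males), expanded to full deme size by one round of reproduction
.found_deme <- function(src, fem_idx, male_idx, n_f, n_m) {
  list(
    Xf1 = src$Xf1[fem_idx, , drop = FALSE][rep_len(seq_along(fem_idx), n_f), , drop = FALSE],
    Xf2 = src$Xf2[fem_idx, , drop = FALSE][rep_len(seq_along(fem_idx), n_f), , drop = FALSE],
    Xm  = src$Xm[male_idx, , drop = FALSE][rep_len(seq_along(male_idx), n_m), , drop = FALSE],
    Ym  = src$Ym[male_idx, , drop = FALSE][rep_len(seq_along(male_idx), n_m), , drop = FALSE],
    rf1 = rep_len(src$rf1[fem_idx], n_f), rf2 = rep_len(src$rf2[fem_idx], n_f),
    rxm = rep_len(src$rxm[male_idx], n_m), rym = rep_len(src$rym[male_idx], n_m),
    if1 = rep_len(src$if1[fem_idx], n_f), if2 = rep_len(src$if2[fem_idx], n_f),
    ixm = rep_len(src$ixm[male_idx], n_m), iym = rep_len(src$iym[male_idx], n_m),
    of1 = rep_len(src$of1[fem_idx], n_f), of2 = rep_len(src$of2[fem_idx], n_f),
    oxm = rep_len(src$oxm[male_idx], n_m), oym = rep_len(src$oym[male_idx], n_m)
  )
}

.region_localities <- list(SE_refugia = 1:10, Pannonian = 11:19,
                           NW_Europe = 20:30)

#' Simulate one sex-linked marker
#'
#' Forward simulation of X/Y gametologs: an ancestral haplotype evolves in
#' a refugial deme; the Pannonian deme is founded from it, and the
#' NW-Europe deme is founded `t_split` generations before the present
#' through a `bottleneck`-sized founder group, after which its male
#' recombination probability switches to `nw_recomb_prob`. Each male
#' meiosis exchanges X/Y sequence with the deme's recombination probability
#' at a single uniform crossover point. Substitutions, stepwise repeat
#' mutation and rare indel flips act on every transmitted gamete. Sampled
#' individuals are rendered into a gapped alignment formatted exactly as
#' [read_alignment()] expects (identical allele pairs become one `"ab"`
#' record), with ground truth per allele.
#'
#' @param params a [sim_params()] object.
#' @return list with `marker` (an `aligned_marker`), `regions` (a region
#'   map), `truth` (data.frame: allele label, chromosome `X`/`Y`, NW
#'   founder haplotype id or `NA`), `rec_events` (recombination event log:
#'   generation, deme, events), `annotations` (the true repeat and indel
#'   annotations in alignment coordinates).
#' @export
simulate_marker <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)

  L <- p$seq_len
  rep_pos <- max(2L, L %/% 3L)        # repeat anchored after this backbone site
  ind_pos <- max(rep_pos + 2L, (2L * L) %/% 3L)
  indel_size <- if (length(p$indel_size) > 1L) {
    sample(seq(p$indel_size[1L], p$indel_size[2L]), 1L)
  } else p$indel_size
  indel_seq <- sample.int(4L, indel_size, replace = TRUE)
  anc <- sample.int(4L, L, replace = TRUE)
  n_f <- p$deme_females; n_m <- p$deme_males
  r_glob <- p$male_recomb_prob
  r_nw <- if (is.na(p$nw_recomb_prob)) r_glob else p$nw_recomb_prob

  demes <- list(SE_refugia = .founder_deme(n_f, n_m, anc, p$repeat_copies))
  G_total <- p$t_burnin + p$t_pann_gap + p$t_split
  t_pann <- p$t_pann_gap + p$t_split   # generations before present
  rec_log <- list()
  for (gen in seq_len(G_total)) {
    to_go <- G_total - gen             # generations remaining after this one
    for (nm in names(demes)) {
      r_here <- if (nm == "NW_Europe") r_nw else r_glob
      nd <- .next_generation(demes[[nm]], r_here, p, rep_pos, ind_pos)
      ev <- attr(nd, "rec_events")
      if (ev > 0L) {
        rec_log[[length(rec_log) + 1L]] <-
          data.frame(generation = gen, deme = nm, events = ev)
      }
      demes[[nm]] <- nd
    }
    if (to_go == t_pann) {
      nf_found <- max(1L, p$pann_founders %/% 2L)
      nm_found <- max(1L, p$pann_founders - nf_found)
      demes$Pannonian <- .found_deme(
        demes$SE_refugia,
        sample.int(n_f, min(nf_found, n_f)),
        sample.int(n_m, min(nm_found, n_m)), n_f, n_m)
    }
    if (to_go == p$t_split) {
      nf_found <- max(1L, p$bottleneck %/% 2L)
      nm_found <- max(1L, p$bottleneck - nf_found)
      fem_idx <- sample.int(n_f, min(nf_found, n_f))
      male_idx <- sample.int(n_m, min(nm_found, n_m))
      nw <- .found_deme(demes$Pannonian, fem_idx, male_idx, n_f, n_m)
      # tag NW founder haplotypes
      nw$of1 <- rep_len(seq_along(fem_idx) * 10L + 1L, n_f)
      nw$of2 <- rep_len(seq_along(fem_idx) * 10L + 2L, n_f)
      nw$oxm <- rep_len(seq_along(male_idx) * 100L + 1L, n_m)
      nw$oym <- rep_len(seq_along(male_idx) * 100L + 2L, n_m)
      demes$NW_Europe <- nw
    }
  }

  # sample individuals and render the alignment
  recs <- list()
  for (reg in names(p$n_sample)) {
    d <- demes[[reg]]
    if (is.null(d)) stop("region ", reg, " was never founded", call. = FALSE)
    ns <- p$n_sample[[reg]]
    locs <- .region_localities[[reg]]
    fi <- sample.int(n_f, ns[["F"]])
    mi <- sample.int(n_m, ns[["M"]])
    for (k in seq_along(fi)) {
      recs[[length(recs) + 1L]] <- list(
        region = reg, sex = "F",
        locality = locs[1L + (k - 1L) %% length(locs)], sample_no = k,
        a1 = list(seq = d$Xf1[fi[k], ], rep = d$rf1[fi[k]],
                  ind = d$if1[fi[k]], chrom = "X", origin = d$of1[fi[k]]),
        a2 = list(seq = d$Xf2[fi[k], ], rep = d$rf2[fi[k]],
                  ind = d$if2[fi[k]], chrom = "X", origin = d$of2[fi[k]]))
    }
    for (k in seq_along(mi)) {
      recs[[length(recs) + 1L]] <- list(
        region = reg, sex = "M",
        locality = locs[1L + (k - 1L) %% length(locs)], sample_no = k,
        a1 = list(seq = d$Xm[mi[k], ], rep = d$rxm[mi[k]],
                  ind = d$ixm[mi[k]], chrom = "X", origin = d$oxm[mi[k]]),
        a2 = list(seq = d$Ym[mi[k], ], rep = d$rym[mi[k]],
                  ind = d$iym[mi[k]], chrom = "Y", origin = d$oym[mi[k]]))
    }
  }

  max_copies <- max(vapply(recs, function(r) max(r$a1$rep, r$a2$rep), 1L))
  motif_chars <- strsplit(p$repeat_motif, "")[[1L]]
  rep_width <- max_copies * length(motif_chars)
  bases <- c("A", "C", "G", "T")
  render <- function(a) {
    bb <- bases[a$seq]
    rep_block <- c(rep(motif_chars, a$rep),
                   rep("-", rep_width - a$rep * length(motif_chars)))
    ind_block <- if (a$ind == 1L) bases[indel_seq] else rep("-", indel_size)
    c(bb[1:rep_pos], rep_block, bb[(rep_pos + 1L):ind_pos], ind_block,
      if (ind_pos < L) bb[(ind_pos + 1L):L])
  }
  labels <- character(0)
  seq_rows <- list()
  truth_rows <- list()
  for (r in recs) {
    s1 <- render(r$a1); s2 <- render(r$a2)
    base <- paste(r$locality, r$sex, r$sample_no, sep = "_")
    identical_alleles <- identical(s1, s2)
    if (identical_alleles) {
      lab <- paste0(base, "_ab")
      labels <- c(labels, lab)
      seq_rows[[length(seq_rows) + 1L]] <- s1
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        label = lab, region = r$region, sex = r$sex,
        chromosome = paste(sort(unique(c(r$a1$chrom, r$a2$chrom))),
                           collapse = "/"),
        founder_id = r$a1$origin, stringsAsFactors = FALSE)
    } else {
      for (tag in c("a", "b")) {
        a <- if (tag == "a") r$a1 else r$a2
        lab <- paste0(base, "_", tag)
        labels <- c(labels, lab)
        seq_rows[[length(seq_rows) + 1L]] <- if (tag == "a") s1 else s2
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          label = lab, region = r$region, sex = r$sex,
          chromosome = a$chrom, founder_id = a$origin,
          stringsAsFactors = FALSE)
      }
    }
  }
  seqs <- do.call(rbind, seq_rows)
  marker <- aligned_marker(seqs, labels, p$marker)
  regs <- region_map(unlist(.region_localities),
                     rep(names(.region_localities),
                         lengths(.region_localities)))
  ann <- list(
    repeat_ann = repeat_annotation(p$marker, rep_pos + 1L,
                                   rep_pos + rep_width, p$repeat_motif),
    indel_ann = indel_annotation(p$marker, rep_pos + rep_width + 1L +
                                   (ind_pos - rep_pos),
                                 rep_pos + rep_width + (ind_pos - rep_pos) +
                                   indel_size)
  )
  list(marker = marker, regions = regs,
       truth = do.call(rbind, truth_rows),
       rec_events = if (length(rec_log)) do.call(rbind, rec_log) else
         data.frame(generation = integer(), deme = character(),
                    events = integer()),
       annotations = ann, params = p)
}

#' Simulate a multi-marker study and write its files
#'
#' Runs [simulate_marker()] for each parameter set and writes the file
#' bundle the pipeline consumes: one gapped FASTA per marker, a
#' locality-to-region TSV, and one ground-truth TSV per marker.
#'
#' @param params_list list of [sim_params()] objects with distinct marker
#'   names.
#' @param dir output directory (created if needed). `NULL` skips writing.
#' @return list of per-marker simulation results (see [simulate_marker()]),
#'   with an attribute `files` naming what was written.
#' @export
simulate_study <- function(params_list, dir = NULL) {
  if (inherits(params_list, "sim_params")) params_list <- list(params_list)
  nms <- vapply(params_list, function(p) p$marker, "")
  if (anyDuplicated(nms)) {
    stop("clashing marker names: ", paste(nms[duplicated(nms)],
                                          collapse = ", "), call. = FALSE)
  }
  sims <- lapply(params_list, simulate_marker)
  names(sims) <- nms
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sims) {
      fa <- file.path(dir, paste0(s$params$marker, ".fasta"))
      write_alignment(s$marker, fa)
      tr <- file.path(dir, paste0(s$params$marker, "_truth.tsv"))
      utils::write.table(s$truth, tr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, fa, tr)
    }
    rm_path <- file.path(dir, "regions.tsv")
    rm_tab <- data.frame(locality = unlist(.region_localities),
                         region = rep(names(.region_localities),
                                      lengths(.region_localities)))
    utils::write.table(rm_tab, rm_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, rm_path)
  }
  attr(sims, "files") <- files
  sims
}

#' Default three-marker study parameters
#'
#' Parameter sets emulating the three markers of the motivating study: a
#' long polymorphic marker with a repeat tract (992 bp, 53 individuals), a
#' mid-length marker with a repeat tract and a large indel (504 bp, 33
#' individuals), and a short marker (411 bp, 16 individuals).
#'
#' @param seed integer seed; per-marker seeds are derived from it.
#' @param ... overrides applied to every marker's [sim_params()] call.
#' @return list of three `sim_params` objects.
#' @export
default_study_params <- function(seed = 1L, ...) {
  list(
    sim_params(marker = "marker_long", seq_len = 992L,
               n_sample = list(SE_refugia = c(F = 9L, M = 9L),
                               Pannonian = c(F = 8L, M = 9L),
                               NW_Europe = c(F = 8L, M = 10L)),
               seed = seed, ...),
    sim_params(marker = "marker_mid", seq_len = 504L,
               n_sample = list(SE_refugia = c(F = 6L, M = 6L),
                               Pannonian = c(F = 5L, M = 6L),
                               NW_Europe = c(F = 5L, M = 5L)),
               seed = seed + 1L, ...),
    sim_params(marker = "marker_short", seq_len = 411L,
               indel_rate = 0, repeat_step_rate = 0,
               n_sample = list(SE_refugia = c(F = 3L, M = 3L),
                               Pannonian = c(F = 2L, M = 3L),
                               NW_Europe = c(F = 2L, M = 3L)),
               seed = seed + 2L, ...)
  )
}

#' Dominance of the NW male-specific Y haplotype
#'
#' Summarises, from a [simulate_marker()] result, how strongly one haplotype
#' dominates the Y copies of NW-Europe males: the modal share of identical
#' full-alignment haplotypes among NW males' Y-slot alleles, and whether that
#' haplotype is male-specific (carried by no female allele range-wide). A
#' run with `share >= 0.5` and `male_specific = TRUE` reproduces the
#' fixed-Y-haplotype pattern expected after a serially bottlenecked
#' expansion without X-Y recombination.
#'
#' @param sim result of [simulate_marker()].
#' @return list with `share` (modal Y-haplotype frequency among NW males),
#'   `male_specific` (logical), `dominant` (`share >= 0.5 && male_specific`).
#' @export
dominant_y_share <- function(sim) {
  key <- apply(sim$marker$seq, 1L, paste, collapse = "")
  tr <- sim$truth
  al <- sim$marker$alleles
  k <- key[match(tr$label, al$label)]
  y_nw <- k[tr$region == "NW_Europe" & tr$sex == "M" &
              grepl("Y", tr$chromosome, fixed = TRUE)]
  if (!length(y_nw)) stop("no NW male Y alleles in simulation", call. = FALSE)
  f_keys <- k[tr$sex == "F"]
  tab <- sort(table(y_nw), decreasing = TRUE)
  share <- tab[[1L]] / sum(tab)
  male_specific <- !(names(tab)[1L] %in% f_keys)
  list(share = share, male_specific = male_specific,
       dominant = share >= 0.5 && male_specific)
}
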