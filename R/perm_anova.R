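# F statistics are computed from QR projections of the (possibly permuted)
# response onto nested design matrices, so that thousands of permutation
# replicates reduce to one matrix product per model. Validated in the test
# suite against anova(lm()) (Type I) and car::Anova (Type II).

.check_cells <- function(mt, mf) {
  fac <- attr(mt, "factors")
  labels <- attr(mt, "term.labels")
  for (i in seq_along(labels)) {
    vars <- rownames(fac)[fac[, i] > 0]
    cols <- mf[vars]
    if (!all(vapply(cols, function(v) is.factor(v) || is.character(v), TRUE)))
      next
    tab <- table(lapply(cols, factor))
    if (length(vars) == 1L) {
      if (length(tab) < 2L) {
        stop("factor '", vars, "' has fewer than two observed levels",
             call. = FALSE)
      }
      if (any(tab < 2L)) {
        stop("level '", names(tab)[which(tab < 2L)[1L]], "' of factor '",
             vars, "' has fewer than 2 observations", call. = FALSE)
      }
    } else if (any(tab == 0L)) {
      empty <- which(tab == 0L, arr.ind = TRUE)[1L, , drop = TRUE]
      cell <- paste(mapply(function(d, l) dimnames(tab)[[d]][l],
                           seq_along(empty), empty), collapse = ":")
      stop("empty cell '", cell, "' in term '", labels[i], "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# rss of Y (n x B) under the model spanned by qr object
.rss <- function(qrx, Y, ssy) {
  r <- qrx$rank
  qty <- qr.qty(qrx, Y)
  ssy - colSums(qty[seq_len(r), , drop = FALSE]^2)
}

# model skeleton: cumulative (Type I) or marginality-respecting (Type II)
# reduced/full QR pairs per term, plus the full-model QR
.anova_skeleton <- function(formula, data, ss_type = c("I", "II")) {
  ss_type <- match.arg(ss_type)
  mt <- stats::terms(formula, data = data)
  mf <- stats::model.frame(mt, data)
  .check_cells(mt, mf)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  X <- stats::model.matrix(mt, mf)
  asgn <- attr(X, "assign")
  labels <- attr(mt, "term.labels")
  k <- length(labels)
  if (k == 0L) stop("formula has no model terms", call. = FALSE)
  n <- length(y)
  qr_full <- qr(X)
  pairs <- vector("list", k)
  if (ss_type == "I") {
    qrs <- lapply(0:k, function(i) qr(X[, asgn <= i, drop = FALSE]))
    for (i in seq_len(k)) pairs[[i]] <- list(red = qrs[[i]], ful = qrs[[i + 1L]])
  } else {
    fac <- attr(mt, "factors")
    varsets <- lapply(seq_len(k), function(i) rownames(fac)[fac[, i] > 0])
    for (i in seq_len(k)) {
      contains_i <- vapply(seq_len(k), function(j)
        j != i && all(varsets[[i]] %in% varsets[[j]]), TRUE)
      red_terms <- setdiff(seq_len(k)[!contains_i], i)
      red <- qr(X[, asgn %in% c(0L, red_terms), drop = FALSE])
      ful <- qr(X[, asgn %in% c(0L, red_terms, i), drop = FALSE])
      pairs[[i]] <- list(red = red, ful = ful)
    }
  }
  df_term <- vapply(pairs, function(p) p$ful$rank - p$red$rank, 1L)
  df_res <- n - qr_full$rank
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)
  list(mt = mt, mf = mf, y = y, X = X, n = n, labels = labels,
       pairs = pairs, qr_full = qr_full, df_term = df_term,
       df_res = df_res, ss_type = ss_type)
}

# F statistics for each column of Y (n x B); returns k x B matrix
.f_matrix <- function(sk, Y) {
  ssy <- colSums(Y^2)
  rss_full <- .rss(sk$qr_full, Y, ssy)
  ms_res <- rss_full / sk$df_res
  k <- length(sk$labels)
  out <- matrix(0, k, ncol(Y))
  tol <- 1e-10 * pmax(ssy, 1)
  for (i in seq_len(k)) {
    ss_i <- .rss(sk$pairs[[i]]$red, Y, ssy) - .rss(sk$pairs[[i]]$ful, Y, ssy)
    ss_i <- pmax(ss_i, 0)
    f <- (ss_i / sk$df_term[i]) / ms_res
    degen <- ms_res <= tol
    if (any(degen)) {
      f[degen] <- ifelse(ss_i[degen] > tol[degen], Inf, 0)
    }
    out[i, ] <- f
  }
  out
}

#' ANOVA F table
#'
#' Sums of squares and F statistics for a linear model with factor terms,
#' using sequential (Type I, in formula order) or marginality-respecting
#' (Type II) sums of squares; denominators use the full-model residual mean
#' square. Degrees-of-freedom bookkeeping handles unbalanced designs.
#'
#' @param formula model formula, e.g. `pd ~ sex` or `pd ~ sex * region`.
#' @param data data.frame holding the response and factors.
#' @param ss_type `"I"` (sequential, default) or `"II"`.
#' @return data.frame with `term`, `df`, `ss`, `ms`, `F`; residual df and SS
#'   in attributes `df_res`, `ss_res`.
#' @export
anova_f <- function(formula, data, ss_type = c("I", "II")) {
  sk <- .anova_skeleton(formula, data, ss_type)
  Y <- matrix(sk$y, ncol = 1L)
  ssy <- colSums(Y^2)
  rss_full <- .rss(sk$qr_full, Y, ssy)
  ss <- vapply(sk$pairs, function(p)
    .rss(p$red, Y, ssy) - .rss(p$ful, Y, ssy), 1)
  ss <- pmax(ss, 0)
  f <- as.vector(.f_matrix(sk, Y))
  out <- data.frame(term = sk$labels, df = sk$df_term, ss = ss,
                    ms = ss / sk$df_term, F = f, stringsAsFactors = FALSE)
  attr(out, "df_res") <- sk$df_res
  attr(out, "ss_res") <- unname(rss_full)
  out
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation ANOVA of within-individual divergence
#'
#' Fits a fixed-effects ANOVA (one-way or factorial) and attaches
#' permutation p-values to every term: the full F table is recomputed for
#' each of `n_perm` random reassignments of the response, and
#' `p = (1 + #\{F* >= F_obs\}) / (1 + n_perm)` per term. Schemes:
#' \describe{
#'   \item{`"manly"`}{(default) unrestricted shuffling of the raw response
#'     across observations;}
#'   \item{`"freedman_lane"`}{per term, residuals of the reduced model
#'     (without that term) are permuted and added back to its fitted
#'     values.}
#' }
#' With `exact = TRUE` all `n!` orderings are enumerated instead (n <= 9)
#' and the p-value is the exact proportion `#\{F* >= F_obs\} / n!`.
#'
#' @param formula model formula, response on the left (e.g.
#'   `pd ~ sex * region`).
#' @param data data.frame of observations (exclusions applied upstream;
#'   rows with `NA` in model variables are rejected).
#' @param n_perm number of permutation replicates (default 10000).
#' @param scheme permutation scheme, see above.
#' @param ss_type `"I"` sequential (default) or `"II"`.
#' @param exact enumerate all permutations exhaustively.
#' @param seed optional integer seed; recorded in the result. The RNG state
#'   of the session is left untouched.
#' @return object of class `perm_anova`: the [anova_f()] table plus
#'   `p_perm`, with fields `call`, `n_perm`, `scheme`, `ss_type`, `seed`,
#'   `df_res`, `ss_res`, `perm_F` (term x replicate matrix of permuted F),
#'   and the fitted full linear model pieces used by the methods.
#' @examples
#' d <- data.frame(pd = c(1, 2, 3, 4, 5, 6),
#'                 sex = rep(c("F", "M"), each = 3))
#' fit <- perm_anova(pd ~ sex, d, n_perm = 199, seed = 1)
#' summary(fit)
#' @export
perm_anova <- function(formula, data, n_perm = 10000,
                       scheme = c("manly", "freedman_lane"),
                       ss_type = c("I", "II"), exact = FALSE, seed = NULL) {
  scheme <- match.arg(scheme)
  ss_type <- match.arg(ss_type)
  if (!exact && n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  mv <- all.vars(formula)
  if (anyNA(data[mv])) stop("NA in model variables; apply exclusions upstream",
                            call. = FALSE)
  sk <- .anova_skeleton(formula, data, ss_type)
  obs_tab <- anova_f(formula, data, ss_type)
  f_obs <- obs_tab$F
  # round-off guard: permutations that merely regroup identical values must
  # count as reaching the observed statistic
  f_thr <- ifelse(is.finite(f_obs), f_obs - 1e-8 * (1 + abs(f_obs)), f_obs)
  k <- length(sk$labels)
  n <- sk$n

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  if (exact) {
    if (n > 9L) stop("exact enumeration limited to n <= 9", call. = FALSE)
    P <- .all_permutations(n)
    Y <- matrix(sk$y[t(P)], nrow = n)
    perm_F <- .f_matrix(sk, Y)
    p_perm <- rowMeans(perm_F >= f_thr)
    n_perm <- nrow(P)
  } else if (scheme == "manly") {
    Y <- vapply(seq_len(n_perm), function(b) sk$y[sample.int(n)],
                numeric(n))
    perm_F <- .f_matrix(sk, Y)
    p_perm <- (1 + rowSums(perm_F >= f_thr)) / (1 + n_perm)
  } else {
    perm_F <- matrix(0, k, n_perm)
    for (i in seq_len(k)) {
      qred <- sk$pairs[[i]]$red
      e <- qr.resid(qred, sk$y)
      mu <- sk$y - e
      Y <- vapply(seq_len(n_perm), function(b) mu + e[sample.int(n)],
                  numeric(n))
      perm_F[i, ] <- .f_matrix(sk, Y)[i, ]
    }
    p_perm <- (1 + rowSums(perm_F >= f_thr)) / (1 + n_perm)
  }

  obs_tab$p_perm <- p_perm
  coefs <- qr.coef(sk$qr_full, sk$y)
  fit <- drop(sk$X %*% ifelse(is.na(coefs), 0, coefs))
  structure(
    list(table = obs_tab, call = match.call(), n_perm = n_perm,
         scheme = if (exact) "exact" else scheme, ss_type = ss_type,
         seed = seed, df_res = attr(obs_tab, "df_res"),
         ss_res = attr(obs_tab, "ss_res"), perm_F = perm_F,
         coefficients = coefs, fitted.values = fit,
         residuals = sk$y - fit, y = sk$y, terms = sk$mt,
         model = sk$mf),
    class = "perm_anova"
  )
}

#' @export
print.perm_anova <- function(x, digits = 3, ...) {
  cat("Permutation ANOVA (", x$ss_type, " SS, ", x$scheme, " scheme, ",
      x$n_perm, " replicates)\n", sep = "")
  tab <- x$table
  df_res <- x$df_res
  out <- data.frame(term = tab$term,
                    df = paste0(tab$df, ",", df_res),
                    F = round(tab$F, digits),
                    p_perm = signif(tab$p_perm, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.perm_anova <- function(object, ...) {
  tab <- object$table
  tab$df_den <- object$df_res
  tab$ms_res <- object$ss_res / object$df_res
  structure(list(call = object$call, table = tab, n_perm = object$n_perm,
                 scheme = object$scheme, ss_type = object$ss_type,
                 seed = object$seed),
            class = "summary.perm_anova")
}

#' @export
print.summary.perm_anova <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n")
  cat("Permutation scheme:", x$scheme, "| SS type:", x$ss_type,
      "| replicates:", x$n_perm,
      if (!is.null(x$seed)) paste("| seed:", x$seed) else "", "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.perm_anova <- function(object, ...) object$coefficients

#' @export
residuals.perm_anova <- function(object, ...) object$residuals

#' @export
fitted.perm_anova <- function(object, ...) object$fitted.values

#' @export
predict.perm_anova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  cf <- ifelse(is.na(object$coefficients), 0, object$coefficients)
  drop(X[, names(object$coefficients), drop = FALSE] %*% cf)
}

#' @export
plot.perm_anova <- function(x, term = 1L, breaks = 40, ...) {
  f_obs <- x$table$F[term]
  fs <- x$perm_F[term, ]
  fs <- fs[is.finite(fs)]
  graphics::hist(fs, breaks = breaks, main = paste0(
    "Permutation null of F[", x$table$term[term], "]"),
    xlab = "F", ...)
  graphics::abline(v = f_obs, col = "red", lwd = 2)
  invisible(x)
}

#' Sex and sex-by-region tests of p_d
#'
#' Runs, per marker, the one-way sex ANOVA of within-individual pairwise
#' differences pooled over all regions, and — for markers with every
#' sex-by-region cell occupied under the expansion-vs-refugia dichotomy —
#' the two-way sex x region model (sequential SS, order sex, region,
#' interaction). p-values come from the permutation procedure.
#'
#' @param pd a `pd_table` (rows from several markers may be rbind-ed).
#' @param n_perm permutation replicates (default 10000).
#' @param seed optional integer seed.
#' @param two_way_markers character vector of markers to test two-way;
#'   `NULL` (default) auto-selects markers whose four cells are all
#'   occupied with at least 2 observations.
#' @param ... passed to [perm_anova()] (e.g. `scheme`, `ss_type`).
#' @return a `pd_anova_report`: list of per-marker fits plus a flat summary
#'   data.frame (`$summary`).
#' @export
pd_anova_report <- function(pd, n_perm = 10000, seed = NULL,
                            two_way_markers = NULL, ...) {
  stopifnot(is.data.frame(pd), all(c("pd", "sex", "marker") %in% names(pd)))
  fits <- list()
  rows <- list()
  markers <- unique(pd$marker)
  for (i in seq_along(markers)) {
    mk <- markers[i]
    d <- pd[pd$marker == mk, , drop = FALSE]
    d$sex <- factor(d$sex)
    sub_seed <- if (is.null(seed)) NULL else seed + i
    one <- perm_anova(pd ~ sex, d, n_perm = n_perm, seed = sub_seed, ...)
    fits[[paste0(mk, ".one_way")]] <- one
    rows[[length(rows) + 1L]] <- data.frame(
      marker = mk, model = "one_way", term = one$table$term,
      df_num = one$table$df, df_den = one$df_res,
      F = one$table$F, p_perm = one$table$p_perm,
      stringsAsFactors = FALSE)
    do_two <- if (is.null(two_way_markers)) {
      "region" %in% names(d) &&
        all(table(d$sex, region_dichotomy(d$region)) >= 2L)
    } else mk %in% two_way_markers
    if (do_two) {
      d$region2 <- region_dichotomy(d$region)
      two <- perm_anova(pd ~ sex * region2, d, n_perm = n_perm,
                        seed = if (is.null(sub_seed)) NULL else sub_seed + 1000L,
                        ...)
      fits[[paste0(mk, ".two_way")]] <- two
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, model = "two_way", term = two$table$term,
        df_num = two$table$df, df_den = two$df_res,
        F = two$table$F, p_perm = two$table$p_perm,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fits, summary = do.call(rbind, rows)),
            class = "pd_anova_report")
}

#' @export
print.pd_anova_report <- function(x, digits = 3, ...) {
  tab <- x$summary
  tab$F <- round(tab$F, digits)
  tab$p_perm <- signif(tab$p_perm, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
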