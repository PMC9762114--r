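#' Exact test of independence for an r x c contingency table
#'
#' Two-sided Fisher exact test generalized to r x c tables (Freeman-Halton).
#' All tables sharing the observed margins are enumerated and the two-sided
#' p-value is the total probability of tables whose point probability under
#' the multivariate hypergeometric null does not exceed that of the observed
#' table. For 2 x 2 tables the hypergeometric support is used directly. When
#' the number of candidate tables exceeds \code{max_tables} a seeded
#' Monte-Carlo estimate over random tables with the same margins is returned
#' and flagged in the result.
#'
#' @param table matrix (or object coercible to one) of non-negative integer
#'   counts.
#' @param max_tables enumeration budget; beyond it the Monte-Carlo fallback
#'   is used.
#' @param mc_iter number of Monte-Carlo tables for the fallback.
#' @param mc_seed seed for the Monte-Carlo fallback (ignored when the table
#'   is enumerated exactly).
#' @return list with elements \code{p.value}, \code{method} ("exact" or
#'   "monte-carlo"), and \code{n.tables} (tables enumerated or sampled).
#' @examples
#' fisher_exact(matrix(c(4, 7, 5, 2, 32, 21), nrow = 2, byrow = TRUE))$p.value
#' @export
fisher_exact <- function(table, max_tables = 1e7, mc_iter = 1e5, mc_seed = 1L) {
  m <- as.matrix(table)
  stop_if(!is.numeric(m) || anyNA(m), "contingency table must be numeric without NA")
  stop_if(any(m < 0), "contingency table has negative counts")
  stop_if(any(m != floor(m)), "contingency table must contain integer counts")
  # drop empty margins; they carry no information
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(list(p.value = 1, method = "exact", n.tables = 1L))
  }
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  rel_err <- 1 + 1e-7
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- log_const - sum(lgamma(m + 1))

  if (nrow(m) == 2 && ncol(m) == 2) {
    support <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
    probs <- stats::dhyper(support, cs[1], cs[2], rs[1])
    p_obs <- stats::dhyper(m[1, 1], cs[1], cs[2], rs[1])
    p <- sum(probs[probs <= p_obs * rel_err])
    return(list(p.value = min(1, p), method = "exact",
                n.tables = length(support)))
  }

  enum <- .enumerate_margin_tables(rs, cs, max_tables)
  if (!is.null(enum)) {
    keep <- enum$logp <= logp_obs + log(rel_err)
    return(list(p.value = min(1, sum(exp(enum$logp[keep]))),
                method = "exact", n.tables = length(enum$logp)))
  }
  # Monte-Carlo fallback over Patefield-sampled tables with fixed margins
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(mc_seed)
  sims <- stats::r2dtable(mc_iter, rs, cs)
  logp_sim <- vapply(sims, function(t) log_const - sum(lgamma(t + 1)), 0)
  p <- (sum(logp_sim <= logp_obs + log(rel_err)) + 1) / (mc_iter + 1)
  list(p.value = p, method = "monte-carlo", n.tables = mc_iter)
}

# enumerate all tables with the given margins, returning their log point
# probabilities; NULL when the budget is exceeded
.enumerate_margin_tables <- function(rs, cs, max_tables) {
  r <- length(rs)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
  out <- new.env(parent = emptyenv())
  out$logp <- vector("list", 1024L)
  out$k <- 0L
  overflow <- FALSE

  rec_row <- function(i, cap, acc) {
    if (overflow) return()
    if (i == r) { # last row fully determined
      out$k <- out$k + 1L
      if (out$k > max_tables) { overflow <<- TRUE; return() }
      out$logp[[out$k]] <- acc - sum(lgamma(cap + 1))
      return()
    }
    for (x in .compositions(rs[i], cap)) {
      rec_row(i + 1L, cap - x, acc - sum(lgamma(x + 1)))
      if (overflow) return()
    }
  }
  rec_row(1L, cs, log_const)
  if (overflow) return(NULL)
  list(logp = unlist(out$logp[seq_len(out$k)], use.names = FALSE))
}

# all vectors x >= 0 with sum(x) == total and x <= cap, as a list
.compositions <- function(total, cap) {
  k <- length(cap)
  if (k == 1) {
    if (total <= cap[1]) return(list(total)) else return(list())
  }
  res <- list()
  lo <- max(0, total - sum(cap[-1]))
  hi <- min(cap[1], total)
  if (lo > hi) return(res)
  for (x1 in lo:hi) {
    for (rest in .compositions(total - x1, cap[-1])) {
      res[[length(res) + 1L]] <- c(x1, rest)
    }
  }
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper around \code{\link[stats]{wilcox.test}} with the conventions used
#' throughout the package: exact enumeration when both samples together hold
#' at most 20 observations (and no ties), otherwise the normal approximation
#' with continuity correction on midranks.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  assert_numeric(x); assert_numeric(y)
  stop_if(length(x) == 0 || length(y) == 0, "both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied; p = 1")
    return(1)
  }
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

#' Spearman rank correlation
#'
#' Spearman's rho on midranks via \code{\link[stats]{cor.test}}; the p-value
#' uses exact enumeration for n <= 8 (no ties) and the t approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with \code{rho} and \code{p.value}.
#' @export
spearman <- function(x, y) {
  assert_numeric(x); assert_numeric(y)
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 3, "need n >= 3")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "Spearman correlation undefined for constant input")
  exact <- length(x) <= 8 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced), via
#' \code{\link[stats]{p.adjust}}.
#'
#' @param p vector of p-values in [0, 1] (NA allowed and propagated).
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  stop_if(!is.numeric(p), "'p' must be numeric")
  ok <- !is.na(p)
  stop_if(any(p[ok] < 0 | p[ok] > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher's method for combining independent p-values
#'
#' X = -2 * sum(log p) is referred to a chi-squared distribution with 2k
#' degrees of freedom.
#'
#' @param p vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fishers_method <- function(p) {
  assert_numeric(p)
  stop_if(length(p) == 0, "need at least one p-value")
  stop_if(any(p <= 0 | p > 1), "p-values must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

.check_survival_table <- function(surv) {
  assert_cols(surv, c("time", "event", "group"), "surv")
  stop_if(any(surv$time <= 0), "survival times must be positive")
  stop_if(!all(surv$event %in% c(0, 1)), "event must be 0/1")
  stop_if(sum(surv$event) == 0, "no events in survival table")
  invisible(surv)
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' Product-limit estimates per group and the standard log-rank chi-squared
#' statistic (1 d.f.), via the survival package.
#'
#' @param surv data frame with columns \code{time} (> 0), \code{event} (0/1)
#'   and \code{group} (exactly two levels).
#' @return list with \code{fit} (a \code{survfit} object), \code{curves}
#'   (data frame of per-group step estimates), \code{chisq} and
#'   \code{p.value}.
#' @export
km_logrank <- function(surv) {
  .check_survival_table(surv)
  g <- factor(surv$group)
  stop_if(nlevels(g) != 2, "km_logrank requires exactly two groups")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ g)
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  chisq <- unname(sd$chisq)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  curves <- data.frame(group = sub("^g=", "", strata), time = fit$time,
                       n.risk = fit$n.risk, n.event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  list(fit = fit, curves = curves, chisq = chisq,
       p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model for a binary group
#'
#' Partial-likelihood fit with Efron handling of ties, via
#' \code{\link[survival]{coxph}}. The hazard ratio is exp(coefficient) with a
#' Wald 95\% confidence interval and p-value.
#'
#' @param surv data frame with columns \code{time}, \code{event},
#'   \code{group} (two levels; the second level is the exposed group).
#' @return list with \code{hr}, \code{ci} (length-2), \code{p.value},
#'   \code{coef}, \code{se}.
#' @export
cox_univariate <- function(surv) {
  .check_survival_table(surv)
  g <- factor(surv$group)
  stop_if(nlevels(g) != 2, "cox_univariate requires exactly two groups")
  stop_if(any(tapply(surv$event, g, sum) == 0),
          "need at least one event per group")
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ g, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (monotone || !is.finite(beta) || abs(beta) > 15)
    stop("partial likelihood is monotone (groups separate the events); ",
         "penalized (Firth-type) fitting is out of scope", call. = FALSE)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * 1.96 * se),
       p.value = 2 * stats::pnorm(-abs(beta / se)), coef = beta, se = se)
}

#' Iterated Grubbs test for outliers
#'
#' Flags the most extreme observation when the Grubbs statistic
#' G = max|x - mean| / sd exceeds the t-based critical value at level
#' \code{alpha}, then repeats on the reduced sample until no outlier remains
#' (or fewer than 3 observations are left).
#'
#' @param x numeric vector (n >= 3).
#' @param alpha significance level per iteration (default 0.05).
#' @param iterate repeat after removing each flagged point (default TRUE).
#' @return list with \code{outliers} (values flagged, in removal order),
#'   \code{index} (their positions in \code{x}), and \code{statistic} of the
#'   first iteration.
#' @export
grubbs_test <- function(x, alpha = 0.05, iterate = TRUE) {
  assert_numeric(x)
  stop_if(length(x) < 3, "Grubbs test needs n >= 3")
  orig <- x
  idx <- seq_along(x)
  flagged <- integer(0)
  g1 <- NA_real_
  repeat {
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / stats::sd(x)
    if (is.na(g1)) g1 <- g
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= crit) break
    i <- which.max(dev)
    flagged <- c(flagged, idx[i])
    x <- x[-i]; idx <- idx[-i]
    if (!iterate) break
  }
  list(outliers = orig[flagged], index = flagged, statistic = g1)
}
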