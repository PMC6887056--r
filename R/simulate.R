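# Synthetic-literature simulator: unbiased negative/positive control
# studies, and literatures distorted by p-hacking and publication bias.

#' Simulation configuration
#'
#' Parameters of the synthetic-literature generator. The unbiased reference
#' emulates a large collection of treatment–outcome analyses with no
#' significance seeking: "negative" controls have true ratio 1 and
#' "positive" controls an injected increased risk with hazard ratio 1.5.
#' Estimates are normal on the log-ratio scale with a Wald interval, the
#' standard textbook model for a ratio estimate from a regression or
#' survival analysis.
#'
#' @param n_studies Number of studies (default 11968, the size of an
#'   all-pairs design of 17 treatments by 22 outcomes replicated across 4
#'   databases).
#' @param prop_positive Proportion of studies with a true effect (default
#'   0.5).
#' @param positive_ratio True ratio of the positive controls (default 1.5).
#' @param se_min,se_max Range of the log-ratio standard error; one SE per
#'   study is drawn log-uniformly from `[se_min, se_max]` (defaults 0.02 and
#'   0.5), giving a realistic spread of interval widths.
#' @param p_hack_looks Number of analysis attempts per study (default 1 =
#'   no p-hacking). With `k` looks the first significant analysis is the one
#'   reported.
#' @param pub_bias_retention Probability that a *non-significant* study is
#'   retained (published); significant studies are always retained. Default
#'   1 = no publication bias.
#' @param ci_level Confidence level in percent (default 95).
#' @param rounding_digits Decimal places used when results are rendered as
#'   text (default 2; applied at rendering, not to the simulated values).
#' @param seed Optional integer seed; when set, generation is reproducible
#'   and does not disturb the caller's RNG state.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(n_studies = 100, seed = 1)
#' @export
sim_config <- function(n_studies = 11968, prop_positive = 0.5,
                       positive_ratio = 1.5, se_min = 0.02, se_max = 0.5,
                       p_hack_looks = 1, pub_bias_retention = 1,
                       ci_level = 95, rounding_digits = 2, seed = NULL) {
  stopifnot(n_studies >= 1, prop_positive >= 0, prop_positive <= 1,
            positive_ratio > 0, se_min > 0, se_max >= se_min,
            p_hack_looks >= 1, pub_bias_retention > 0,
            pub_bias_retention <= 1, ci_level > 0, ci_level < 100,
            rounding_digits >= 0)
  structure(list(
    n_studies = as.integer(n_studies), prop_positive = prop_positive,
    positive_ratio = positive_ratio, se_min = se_min, se_max = se_max,
    p_hack_looks = as.integer(p_hack_looks),
    pub_bias_retention = pub_bias_retention, ci_level = ci_level,
    rounding_digits = as.integer(rounding_digits), seed = seed),
    class = "sim_config")
}

.z_level <- function(ci_level) qnorm(1 - (1 - ci_level / 100) / 2)

.with_config_seed <- function(config, code) {
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, code)
  } else {
    force(code)
  }
}

#' Simulate Wald interval records for given true effects
#'
#' Draws one estimate per study from a normal distribution on the log-ratio
#' scale and forms the Wald confidence interval
#' `exp(estimate -/+ z * se)`. Under the null (true log ratio 0) the
#' fraction of significant intervals converges to the nominal type-I rate
#' (0.05 at the 95% level).
#'
#' @param true_log_ratio Numeric vector of true log ratios (recycled).
#' @param se Numeric vector of log-scale standard errors, positive.
#' @param ci_level Confidence level in percent (default 95).
#' @return A tibble of interval records: `estimate_type` (`"HR"`),
#'   `point_estimate`, `lower`, `upper`, `ci_level`. Full precision; any
#'   rounding belongs to the rendering step.
#' @examples
#' simulate_study(0, se = 0.1)
#' simulate_study(log(1.5), se = rep(0.2, 5))
#' @export
simulate_study <- function(true_log_ratio, se, ci_level = 95) {
  stopifnot(is.numeric(true_log_ratio), is.numeric(se), all(se > 0))
  n <- max(length(true_log_ratio), length(se))
  true_log_ratio <- rep_len(true_log_ratio, n)
  se <- rep_len(se, n)
  z <- .z_level(ci_level)
  est <- rnorm(n, true_log_ratio, se)
  tibble(estimate_type = "HR",
         point_estimate = exp(est),
         lower = exp(est - z * se),
         upper = exp(est + z * se),
         ci_level = ci_level)
}

#' Simulate p-hacked interval records (repeated analysis looks)
#'
#' Models p-hacking as up to `k_looks` independent analyses of the same true
#' effect: the first statistically significant analysis is the one reported,
#' and if none is significant the last is reported. With `k_looks = 1` this
#' reduces exactly to [simulate_study()]. Under the null the probability of
#' reporting a significant result grows as `1 - (1 - alpha)^k`.
#'
#' @inheritParams simulate_study
#' @param k_looks Integer >= 1, number of analysis attempts per study.
#' @return A tibble as in [simulate_study()] with extra columns
#'   `n_looks_used` (which attempt was reported) and `was_hacked` (reported
#'   attempt beyond the first).
#' @examples
#' apply_p_hacking(0, se = rep(0.1, 5), k_looks = 5)
#' @export
apply_p_hacking <- function(true_log_ratio, se, k_looks = 1, ci_level = 95) {
  stopifnot(k_looks >= 1)
  n <- max(length(true_log_ratio), length(se))
  true_log_ratio <- rep_len(true_log_ratio, n)
  se <- rep_len(se, n)
  z <- .z_level(ci_level)
  looks <- matrix(rnorm(n * k_looks), n, k_looks) * se + true_log_ratio
  sig <- abs(looks) > z * se # CI excludes the null log ratio 0
  idx <- apply(sig, 1, function(s) if (any(s)) which(s)[1] else k_looks)
  est <- looks[cbind(seq_len(n), idx)]
  tibble(estimate_type = "HR",
         point_estimate = exp(est),
         lower = exp(est - z * se),
         upper = exp(est + z * se),
         ci_level = ci_level,
         n_looks_used = as.integer(idx),
         was_hacked = idx > 1L)
}

#' Apply publication bias to a set of interval records
#'
#' Statistically significant records (interval excluding the null value 1)
#' are always retained; non-significant records are retained independently
#' with probability `retention`. Returns the retained records; the full
#' per-record decision is available as attribute `"survived"`.
#'
#' @param records A tibble with `lower` and `upper` columns.
#' @param retention Probability in \[0, 1\] of retaining a non-significant
#'   record; 0 keeps only the significant ones.
#' @param null_value Null value on the ratio scale (default 1).
#' @return The retained subset of `records`, with attribute `survived`
#'   (logical vector over the input rows).
#' @examples
#' recs <- simulate_study(0, se = rep(0.2, 20))
#' apply_publication_bias(recs, retention = 0.3)
#' @export
apply_publication_bias <- function(records, retention, null_value = 1) {
  stopifnot(is.data.frame(records), retention >= 0, retention <= 1)
  sig <- records$lower > null_value | records$upper < null_value
  survived <- sig | runif(nrow(records)) < retention
  out <- records[survived, , drop = FALSE]
  attr(out, "survived") <- survived
  out
}

# shared generator core; bias knobs taken from `config` unless forced
.simulate_corpus <- function(config, force_unbiased = FALSE) {
  looks <- if (force_unbiased) 1L else config$p_hack_looks
  retention <- if (force_unbiased) 1 else config$pub_bias_retention
  .with_config_seed(config, {
    n <- config$n_studies
    se <- exp(runif(n, log(config$se_min), log(config$se_max)))
    positive <- runif(n) < config$prop_positive
    tlr <- ifelse(positive, log(config$positive_ratio), 0)
    recs <- apply_p_hacking(tlr, se, k_looks = looks,
                            ci_level = config$ci_level)
    recs$study_id <- sprintf("study%06d", seq_len(n))
    pub <- apply_publication_bias(recs, retention = retention)
    survived <- attr(pub, "survived")
    truth <- tibble(
      study_id = recs$study_id,
      true_log_ratio = tlr,
      true_positive = positive,
      se = se,
      n_looks_used = recs$n_looks_used,
      was_hacked = recs$was_hacked,
      survived_publication = survived)
    records <- pub |>
      select("study_id", "estimate_type", "point_estimate", "lower",
             "upper", "ci_level")
    list(records = records, truth = truth, config = config)
  })
}

#' Generate an unbiased synthetic literature (negative/positive controls)
#'
#' The bias-free reference corpus: a mixture of negative controls (true
#' ratio 1) and positive controls (true ratio `positive_ratio`, default
#' 1.5), one analysis per study, everything published. Its limit
#' distributions are smooth S-shapes; it is the backdrop against which the
#' distorted corpora are compared. `p_hack_looks = 1` and
#' `pub_bias_retention = 1` are forced regardless of the configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_corpus`: `records` (tibble of interval
#'   records with `study_id`), `truth` (per-study ground truth:
#'   `true_log_ratio`, `true_positive`, `se`, `n_looks_used`, `was_hacked`,
#'   `survived_publication`), and `config`.
#' @examples
#' corpus <- generate_unbiased_corpus(sim_config(n_studies = 50, seed = 1))
#' corpus$records
#' @export
generate_unbiased_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  out <- .simulate_corpus(config, force_unbiased = TRUE)
  structure(out, class = "synthetic_corpus")
}

#' Generate a distorted synthetic literature
#'
#' Applies p-hacking (repeated analysis looks, first significant reported)
#' and then publication bias (significance-dependent retention) to the same
#' study population as [generate_unbiased_corpus()]. With `p_hack_looks = 1`
#' and `pub_bias_retention = 1` it is identical, draw for draw, to the
#' unbiased generator under the same seed.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_corpus` list as in [generate_unbiased_corpus()];
#'   `records` contains only the published studies, `truth` all of them.
#' @examples
#' biased <- generate_biased_corpus(
#'   sim_config(n_studies = 50, p_hack_looks = 5,
#'              pub_bias_retention = 0.3, seed = 1))
#' @export
generate_biased_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  out <- .simulate_corpus(config, force_unbiased = FALSE)
  structure(out, class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$records), " published records of ",
      x$config$n_studies, " studies\n", sep = "")
  cat("  p_hack_looks = ", x$config$p_hack_looks,
      ", pub_bias_retention = ", x$config$pub_bias_retention, "\n", sep = "")
  invisible(x)
}

#' One-row summary of a synthetic corpus
#'
#' @param x A `synthetic_corpus`.
#' @param ... Unused.
#' @return A one-row tibble with the study counts, the published share and
#'   the share of published records that are statistically significant.
#' @method glance synthetic_corpus
#' @export
glance.synthetic_corpus <- function(x, ...) {
  cls <- classify_significance(x$records)
  tibble(n_studies = x$config$n_studies,
         n_published = nrow(x$records),
         prop_published = nrow(x$records) / x$config$n_studies,
         prop_significant = mean(cls$significance != "nonsig"))
}
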