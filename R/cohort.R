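# Seeded synthetic cardiovascular cohort. Distribution parameters are invented
# (the clinical dataset this emulates is access-restricted); they reproduce its
# documented qualitative features: multimodal and heavy-tailed continuous
# marginals, imbalanced binary comorbidities, correlated baseline/follow-up
# measurements, an exact 76.6% male fraction and ages strictly above 30.
# Units: Age years, WT kg, HT cm, DBP mmHg, hA1c %, LDL / T.C. mmol/L.

mixture_mean_var <- function(w, mu, sd) {
  m <- sum(w * mu)
  list(mean = m, var = sum(w * (sd^2 + mu^2)) - m^2)
}

trunc_norm_mean_var <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  list(mean = m, var = v)
}

r_trunc_norm <- function(n, mu, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mu, sd), 1)
  stats::qnorm(u, mu, sd)
}

# Follow-up noise sd targeting cor(baseline, follow-up) = r given baseline sd.
followup_noise_sd <- function(base_sd, r = 0.6) base_sd * sqrt(1 / r^2 - 1)

cohort_truth <- function(n) {
  mix <- function(w, mu, sd, truncate_above = NULL) {
    if (is.null(truncate_above)) {
      mv <- mixture_mean_var(w, mu, sd)
    } else {
      per <- lapply(seq_along(w), function(k) trunc_norm_mean_var(mu[k], sd[k], truncate_above))
      m <- sum(w * vapply(per, `[[`, numeric(1L), "mean"))
      v <- sum(w * vapply(per, function(p) p$var + p$mean^2, numeric(1L))) - m^2
      mv <- list(mean = m, var = v)
    }
    list(type = "mixture", weights = w, means = mu, sds = sd,
         truncate_above = truncate_above, mean = mv$mean, sd = sqrt(mv$var))
  }
  followup <- function(base, delta, r = 0.6) {
    list(type = "followup", base = base, delta = delta, r = r)
  }
  binary <- function(p_yes) {
    list(type = "categorical", categories = c("no", "yes"), probs = c(1 - p_yes, p_yes))
  }

  truth <- list(
    `hA1c.#1` = mix(c(0.55, 0.45), c(5.6, 8.6), c(0.45, 1.2)),
    `DBP.#1` = mix(c(0.75, 0.25), c(74, 90), c(8, 7)),
    `LDL.#1` = mix(c(0.70, 0.30), c(2.6, 4.3), c(0.7, 0.9)),
    `T.C.#1` = mix(c(0.80, 0.20), c(4.6, 6.5), c(0.9, 1.0)),
    `CACS#2.scor` = list(type = "zero_inflated_lognormal", p_zero = 0.35,
                         meanlog = 4.6, sdlog = 1.4),
    `hA1c.#2` = followup("hA1c.#1", delta = -0.4),
    `DBP.#2` = followup("DBP.#1", delta = -3),
    `LDL.#2` = followup("LDL.#1", delta = -0.5),
    `T.C.#2` = followup("T.C.#1", delta = -0.4),
    Age = mix(c(0.62, 0.38), c(52, 69), c(8, 7), truncate_above = 30),
    WT = list(type = "linear_on", base = "HT", intercept = -60, slope = 0.75,
              noise_sd = 10),
    HT = mix(1, 167, 9),
    BMI = list(type = "derived", rule = "WT / (HT / 100)^2"),
    eGFR = list(type = "categorical",
                categories = c("mildly_reduced", "normal", "reduced"),
                probs = c(0.40, 0.45, 0.15)),
    P.STRK = binary(0.07),
    P.MI = binary(0.18),
    A.F = binary(0.10),
    Gender = list(type = "exact_split", categories = c("female", "male"),
                  male_count = round(0.766 * n)),
    CAD.prior = binary(0.40),
    RA = binary(0.06),
    CKD = binary(0.15),
    DLP = binary(0.60),
    DM = binary(0.55),
    HTN = binary(0.70)
  )

  # analytic means/sds used by recovery checks
  for (col in names(truth)) {
    t <- truth[[col]]
    truth[[col]] <- switch(t$type,
      mixture = t,
      zero_inflated_lognormal = {
        m1 <- exp(t$meanlog + t$sdlog^2 / 2)
        m2 <- exp(2 * t$meanlog + 2 * t$sdlog^2)
        t$mean <- (1 - t$p_zero) * m1
        t$sd <- sqrt((1 - t$p_zero) * m2 - t$mean^2)
        t
      },
      followup = {
        base <- truth[[t$base]]
        t$noise_sd <- followup_noise_sd(base$sd, t$r)
        t$mean <- base$mean + t$delta
        t$sd <- sqrt(base$sd^2 + t$noise_sd^2)
        t
      },
      linear_on = {
        base <- truth[[t$base]]
        t$mean <- t$intercept + t$slope * base$mean
        t$sd <- sqrt(t$slope^2 * base$sd^2 + t$noise_sd^2)
        t
      },
      t # derived / categorical: no analytic continuous mean
    )
  }
  structure(list(n = n, male_fraction = 0.766, columns = truth),
            class = "cohort_truth")
}

#' Simulate a reference cardiovascular cohort
#'
#' Generates a fully synthetic patient table with the 13 continuous and 11
#' categorical features of a cardiovascular follow-up cohort: bimodal baseline
#' labs (HbA1c, DBP, LDL, total cholesterol), follow-up values correlated with
#' baseline (target Pearson r = 0.6), a zero-inflated log-normal coronary
#' calcium score (heavy tail), height/weight drawn jointly with BMI computed
#' as `WT / (HT / 100)^2`, age truncated strictly above 30, an exact
#' `round(0.766 * n)` male count, and imbalanced binary comorbidities. The
#' generating parameters are returned as ground truth so recovery can be
#' tested against what was actually simulated.
#'
#' @param n Cohort size (default 218).
#' @param seed Integer seed (default 42); identical seeds give identical cohorts.
#' @return A tibble of `n` records with the ground truth attached as attribute
#'   `"ground_truth"` (see [cohort_ground_truth()]).
#' @export
#' @examples
#' cohort <- simulate_cohort()
#' nrow(cohort) # 218
#' mean(cohort$Gender == "male") # 0.766...
simulate_cohort <- function(n = 218L, seed = 42L) {
  if (length(n) != 1L || !is.finite(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  truth <- cohort_truth(n)
  cols <- truth$columns

  out <- withr::with_seed(as.integer(seed), {
    vals <- list()
    draw_mixture <- function(t) {
      comp <- sample.int(length(t$weights), n, replace = TRUE, prob = t$weights)
      if (is.null(t$truncate_above)) {
        stats::rnorm(n, t$means[comp], t$sds[comp])
      } else {
        r_trunc_norm(n, t$means[comp], t$sds[comp], t$truncate_above)
      }
    }
    # draw in dependency order: mixtures first, then derived quantities
    for (col in names(cols)) {
      t <- cols[[col]]
      if (t$type == "mixture") vals[[col]] <- draw_mixture(t)
    }
    for (col in names(cols)) {
      t <- cols[[col]]
      vals[[col]] <- switch(t$type,
        mixture = vals[[col]],
        zero_inflated_lognormal = {
          zero <- stats::runif(n) < t$p_zero
          x <- stats::rlnorm(n, t$meanlog, t$sdlog)
          x[zero] <- 0
          x
        },
        followup = vals[[t$base]] + t$delta + stats::rnorm(n, 0, t$noise_sd),
        linear_on = t$intercept + t$slope * vals[[t$base]] +
          stats::rnorm(n, 0, t$noise_sd),
        derived = vals[["WT"]] / (vals[["HT"]] / 100)^2,
        categorical = t$categories[
          sample.int(length(t$categories), n, replace = TRUE, prob = t$probs)],
        exact_split = sample(rep(t$categories, c(n - t$male_count, t$male_count)))
      )
    }
    tibble::as_tibble(vals[names(cols)])
  })
  attr(out, "ground_truth") <- truth
  out
}

#' Ground truth of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return The `cohort_truth` used to generate it: per-column generating
#'   parameters plus analytic means/sds where tractable.
#' @export
cohort_ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) stop("no ground truth attached; was this simulated?", call. = FALSE)
  gt
}

#' Schema of the reference cohort
#'
#' @return A [table_schema()] declaring the cohort's 13 continuous and 11
#'   categorical columns in table order.
#' @export
cohort_schema <- function() {
  cols <- cohort_truth(1L)$columns
  kinds <- vapply(cols, function(t) {
    if (t$type %in% c("categorical", "exact_split")) "categorical" else "continuous"
  }, character(1L))
  table_schema(continuous = names(kinds)[kinds == "continuous"],
               categorical = names(kinds)[kinds == "categorical"],
               order = names(kinds))
}

#' Write a cohort bundle to disk
#'
#' Writes the cohort CSV, its column-kind YAML configuration, and the
#' generating ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`cohort.csv`, `columns.yaml`,
#'   `ground_truth.json`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "columns.yaml", "ground_truth.json"))
  readr::write_csv(cohort, paths[1L])
  write_schema_yaml(cohort_schema(), paths[2L])
  gt <- cohort_ground_truth(cohort)
  jsonlite::write_json(gt, paths[3L], auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(paths)
}
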