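# Paired statistical comparison of templates over atlas regions, with
# Bonferroni correction, and the end-to-end template-comparison experiment.

#' Paired t-test
#'
#' Two-sided paired t-test on per-subject values:
#' `t = mean(x - y) / (sd(x - y) / sqrt(n))`, `df = n - 1`.  All-zero
#' differences give `t = 0, p = 1`; zero variance with a nonzero mean gives
#' `p = 0` with a degenerate-variance warning.
#'
#' @param x,y Numeric vectors of equal length (n >= 2), paired by position.
#' @return List with `t`, `p`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1))
    warning("degenerate variance: identical nonzero differences; p = 0")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  alpha / m
}

reference_channels <- function(x) {
  if (inherits(x, "brain_template")) x$channels
  else if (is_volume(x)) list(x)
  else if (is.list(x) && all(vapply(x, is_volume, TRUE))) x
  else stop("common_reference must be a template or volume(s)", call. = FALSE)
}

#' Compare two templates on held-out subjects
#'
#' Implements the full validation loop: every validation subject is
#' registered to each template; per-voxel displacement and absolute
#' log-Jacobian maps are computed in each template's space and transported
#' to a common reference space through a bridge deformation (obtained by
#' registering each template to the reference); region means are collected
#' per subject after the minimum-volume exclusion; and a paired t-test with
#' Bonferroni correction (m = number of retained regions, per metric
#' family) is run per region for both metrics.
#'
#' @param validation_subjects List of subjects (disjoint from both
#'   templates' construction sets, checked via subject ids).
#' @param template_a,template_b [build_template()] results.
#' @param atlas A [label_atlas()] on the common-reference grid.
#' @param common_reference Template or volume defining the common space;
#'   default `template_a`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_volume_mm3 Region-volume exclusion threshold (default 500).
#' @param params [registration_params()] used for all registrations.
#' @return An object of class `template_comparison`: `displacement` and
#'   `log_jacobian` region tibbles (`region_id`, `name`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `t_statistic`, `p_value`, `significant`,
#'   `direction`), and a `summary` tibble.
#' @export
compare_templates <- function(validation_subjects, template_a, template_b,
                              atlas, common_reference = NULL,
                              alpha = 0.05, min_volume_mm3 = 500,
                              params = registration_params()) {
  if (length(validation_subjects) == 0)
    stop("empty validation list", call. = FALSE)
  val_ids <- vapply(seq_along(validation_subjects), function(i)
    subject_ident(validation_subjects[[i]], i), "")
  build_ids <- c(template_a$ids, template_b$ids)
  overlap <- intersect(val_ids, build_ids)
  if (length(overlap))
    stop(sprintf("validation subjects overlap template construction sets: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  common_reference <- common_reference %||% template_a
  ref_ch <- reference_channels(common_reference)
  stopifnot_same_grid(atlas$labels, ref_ch[[1]], "atlas and reference")
  same_templates <- identical(template_a, template_b)
  bridge_for <- function(tpl) {
    if (identical(tpl$channels, ref_ch))
      return(zero_field(dim(ref_ch[[1]]), vol_spacing(ref_ch[[1]]),
                        vol_affine(ref_ch[[1]])))
    nch <- min(length(tpl$channels), length(ref_ch))
    register_pair(tpl$channels[seq_len(nch)], ref_ch[seq_len(nch)],
                  params)$deformation
  }
  bridges <- list(a = bridge_for(template_a),
                  b = if (same_templates) NULL else bridge_for(template_b))
  subject_metrics <- function(subject, tpl, bridge) {
    ch <- subject_channel_volumes(subject)
    nch <- min(length(ch), length(tpl$channels))
    reg <- register_pair(ch[seq_len(nch)], tpl$channels[seq_len(nch)], params)
    disp <- displacement_map(reg$deformation)
    alj <- abs_log_jacobian(jacobian_map(reg$deformation, log_output = TRUE))
    region_summary(to_common_space(disp, bridge),
                   to_common_space(alj, bridge),
                   atlas, min_volume_mm3)
  }
  n <- length(validation_subjects)
  res_a <- vector("list", n); res_b <- vector("list", n)
  for (i in seq_len(n)) {
    res_a[[i]] <- subject_metrics(validation_subjects[[i]], template_a,
                                  bridges$a)
    res_b[[i]] <- if (same_templates) res_a[[i]]
    else subject_metrics(validation_subjects[[i]], template_b, bridges$b)
  }
  regions <- res_a[[1]][, c("region_id", "name", "volume_mm3")]
  m <- nrow(regions)
  threshold <- bonferroni_threshold(alpha, m)
  build_report <- function(col) {
    xa <- sapply(res_a, function(r) r[[col]])  # regions x subjects
    xb <- sapply(res_b, function(r) r[[col]])
    if (m == 1) { xa <- matrix(xa, 1); xb <- matrix(xb, 1) }
    rows <- lapply(seq_len(m), function(r) {
      tt <- paired_t(xa[r, ], xb[r, ])
      ma <- mean(xa[r, ]); mb <- mean(xb[r, ])
      sig <- tt$p < threshold
      dir <- if (!sig || ma == mb) "none" else if (ma < mb) "A<B" else "B<A"
      tibble::tibble(region_id = regions$region_id[r],
                     name = regions$name[r],
                     mean_a = ma, sd_a = sd(xa[r, ]),
                     mean_b = mb, sd_b = sd(xb[r, ]),
                     t_statistic = tt$t, p_value = tt$p,
                     significant = sig, direction = dir)
    })
    do.call(rbind, rows)
  }
  rep_disp <- build_report("mean_displacement_mm")
  rep_jac <- build_report("mean_abs_log_jacobian")
  summarize <- function(rep, metric) {
    tibble::tibble(
      metric = metric,
      n_regions_tested = m,
      n_significant_A_less = sum(rep$direction == "A<B"),
      n_significant_B_less = sum(rep$direction == "B<A"),
      alpha = alpha, threshold = threshold,
      overall_mean_a = mean(rep$mean_a), overall_mean_b = mean(rep$mean_b)
    )
  }
  structure(list(displacement = rep_disp, log_jacobian = rep_jac,
                 summary = rbind(summarize(rep_disp, "displacement"),
                                 summarize(rep_jac, "abs_log_jacobian")),
                 n_validation = n),
            class = "template_comparison")
}

#' @export
print.template_comparison <- function(x, ...) {
  cat(sprintf("<template_comparison> %d validation subjects, %d regions\n",
              x$n_validation, x$summary$n_regions_tested[1]))
  print(x$summary)
  invisible(x)
}

#' Tidy a template comparison
#'
#' @param x A `template_comparison`.
#' @param metric `"displacement"` or `"abs_log_jacobian"`.
#' @param ... Unused.
#' @return The per-region report tibble for the chosen metric.
#' @export
tidy.template_comparison <- function(x,
                                     metric = c("displacement",
                                                "abs_log_jacobian"),
                                     ...) {
  metric <- match.arg(metric)
  if (metric == "displacement") x$displacement else x$log_jacobian
}

#' @export
glance.template_comparison <- function(x, ...) x$summary

#' Plot per-region template comparison
#'
#' @param object A `template_comparison`.
#' @param metric Metric to plot.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @export
autoplot.template_comparison <- function(object,
                                         metric = c("displacement",
                                                    "abs_log_jacobian"),
                                         ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot", call. = FALSE)
  metric <- match.arg(metric)
  rep <- tidy.template_comparison(object, metric)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$mean_b, y = .data$mean_a,
                                    colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "template B region mean", y = "template A region mean",
                  title = sprintf("Region-wise %s", metric))
}

# Spec with its strata replaced by a single stratum of n subjects
# (balanced sexes; odd n gives the extra subject to the men).
spec_with_n <- function(spec, n, label = "60-64") {
  spec$strata <- data.frame(label = label, n_men = ceiling(n / 2),
                            n_women = floor(n / 2))
  spec
}

#' Run a synthetic template-comparison experiment
#'
#' End-to-end driver: simulate populations, build two templates, compare
#' them on held-out subjects.  Three designs are available:
#' * `"ethnicity"`: template A from the base population, template B from a
#'   shifted population (enlarged parahippocampal-analogue structures);
#'   validation subjects held out from the base population.
#' * `"sample_size"`: templates from disjoint samples of sizes `n_a` and
#'   `n_b` of one population.
#' * `"null"`: templates from disjoint equal-size samples of one
#'   population.
#'
#' @param design One of `"ethnicity"`, `"sample_size"`, `"null"`.
#' @param spec Base [phantom_spec()] (its strata are replaced by the
#'   experiment's sample sizes).
#' @param n_a,n_b Construction sample sizes for templates A and B.
#' @param n_validation Held-out validation sample size.
#' @param seed Experiment seed (population seeds are derived from it).
#' @param schedule Template-builder `(outer, inner)` schedule.
#' @param params [registration_params()] for all registrations.
#' @param alpha,min_volume_mm3 Passed to [compare_templates()].
#' @param shift_scale Structure-size multiplier for the shifted population
#'   (ethnicity design only).
#' @return A [compare_templates()] result with the two templates attached
#'   as attributes `template_a` / `template_b`.
#' @export
run_template_experiment <- function(design = c("ethnicity", "sample_size",
                                               "null"),
                                    spec = phantom_spec(),
                                    n_a = 20, n_b = 20, n_validation = 10,
                                    seed = 1,
                                    schedule = c(3L, 4L),
                                    params = registration_params(
                                      channel_weights = phantom_channel_weights()),
                                    alpha = 0.05, min_volume_mm3 = 500,
                                    shift_scale = 1.3) {
  design <- match.arg(design)
  seed <- as.integer(seed)
  spec_a <- spec_with_n(spec, n_a)
  spec_b <- switch(design,
                   ethnicity = {
                     s <- phantom_spec(
                       grid_shape = spec$grid_shape,
                       spacing_mm = spec$spacing_mm,
                       brain_semi_axes_mm = spec$brain_semi_axes_mm,
                       structure_size_scale = c(parahippocampal = shift_scale,
                                                hippocampus = sqrt(shift_scale)),
                       class_intensities = spec$class_intensities,
                       noise_sd = spec$noise_sd,
                       bias_amplitude = spec$bias_amplitude,
                       warp_sd_mm = spec$warp_sd_mm,
                       warp_smoothness_mm = spec$warp_smoothness_mm,
                       strata = spec$strata,
                       sex_size_factor = spec$sex_size_factor,
                       age_shrink = spec$age_shrink)
                     spec_with_n(s, n_b)
                   },
                   sample_size = spec_with_n(spec, n_b),
                   null = spec_with_n(spec, n_b))
  pop_a <- generate_population(spec_a, seed = seed * 11 + 1, id_prefix = "A")
  pop_b <- generate_population(spec_b, seed = seed * 11 + 2, id_prefix = "B")
  val <- generate_population(spec_with_n(spec, n_validation),
                             seed = seed * 11 + 3, id_prefix = "V")
  if (spec$bias_amplitude > 0) {
    pop_a <- lapply(pop_a, preprocess_phantom)
    pop_b <- lapply(pop_b, preprocess_phantom)
    val <- lapply(val, preprocess_phantom)
  }
  tpl_a <- build_template(initial_import(pop_a), schedule = schedule,
                          params = params)
  tpl_b <- build_template(initial_import(pop_b), schedule = schedule,
                          params = params)
  atlas <- make_atlas(spec)
  # neutral common reference (the analytic population-mean anatomy) so
  # both templates' metric maps undergo one transport interpolation each;
  # referencing one of the built templates treats them asymmetrically
  mp <- mean_phantom(spec)
  ref <- c(list(mp$t1), mp$tissues$maps)
  cmp <- compare_templates(val, tpl_a, tpl_b, atlas,
                           common_reference = ref, alpha = alpha,
                           min_volume_mm3 = min_volume_mm3, params = params)
  attr(cmp, "template_a") <- tpl_a
  attr(cmp, "template_b") <- tpl_b
  attr(cmp, "design") <- design
  cmp
}
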