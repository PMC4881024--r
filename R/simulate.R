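#' Configuration of an in-silico kinome profiling experiment
#'
#' Describes the virtual biological experiment used to validate and benchmark
#' the normalization methods: per patient, one control and one treatment
#' slide are generated, each spot intensity (log2, dimensionless) being the
#' sum of a random basic intensity, inter-patient biological variation, a
#' treatment effect for induced substrates, a smooth intraslide gradient
#' field, a slide-wide array effect, and per-replicate spot error.
#'
#' @param n_patients Number of virtual patients (default 8).
#' @param layout Slide [array_layout()] (default 3 sets of 32 x 32).
#' @param mu_basic,sigma_basic Mean and SD of the per-substrate basic
#'   intensity (default N(10, 1.5)).
#' @param sigma_patient SD of the per-patient, per-substrate biological
#'   variation (default 0.5).
#' @param effect_size Treatment effect E in log2 units added to induced
#'   substrates on treatment slides (default 0.8, i.e. effect/spot-error = 2).
#' @param n_induced Number of induced substrates (default 197, organized as 2
#'   pathways of 18 kinases by [annotation_fixture()]).
#' @param gradient_strength Max - min range, in log2 units, of the intraslide
#'   gradient fields (default 1.0, the midpoint of the 0.4-1.5 range seen on
#'   real slides). Set `use_gradients = FALSE` to disable.
#' @param n_gradient_fields Number of candidate gradient fields, one of which
#'   is drawn independently for every slide (default 15).
#' @param use_gradients,use_array_effects Toggles for the two systematic
#'   technical components.
#' @param array_effect_range Range of the uniform slide-wide array effect
#'   (default `c(-2, 0)` log2 units).
#' @param sigma_error SD of the per-replicate spot error (default 0.4).
#' @param off_fraction Fraction of substrates rendered as off-spots:
#'   background-level noise, pre-flagged (`ks` and `overall` set), excluded
#'   from normalization like any flagged spot (default 0).
#' @param pathway_mode Add the two pathway-analysis variation sources:
#'   per-patient biological effect-size variation N(0, `bio_sd`) and
#'   per-substrate technical effect-size variation
#'   U(-`tech_halfwidth`, `tech_halfwidth`).
#' @param bio_sd,tech_halfwidth Parameters of the two extra sources (defaults
#'   0.4 and 0.2; use `tech_halfwidth = 0.33 * effect_size` in effect-size
#'   sweeps).
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_patients = 8L, layout = array_layout(),
                       mu_basic = 10, sigma_basic = 1.5,
                       sigma_patient = 0.5, effect_size = 0.8,
                       n_induced = 197L, gradient_strength = 1.0,
                       n_gradient_fields = 15L,
                       use_gradients = TRUE, use_array_effects = TRUE,
                       array_effect_range = c(-2, 0), sigma_error = 0.4,
                       off_fraction = 0, pathway_mode = FALSE,
                       bio_sd = 0.4, tech_halfwidth = 0.2) {
  stopifnot(n_patients >= 1, sigma_basic >= 0, sigma_patient >= 0,
            sigma_error >= 0, off_fraction >= 0, off_fraction < 1,
            gradient_strength >= 0, length(array_effect_range) == 2)
  n_sub <- n_substrates(layout)
  if (n_induced >= n_sub) stop("induced fraction must be < 1", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients), layout = layout,
         mu_basic = mu_basic, sigma_basic = sigma_basic,
         sigma_patient = sigma_patient, effect_size = effect_size,
         n_induced = as.integer(n_induced),
         gradient_strength = gradient_strength,
         n_gradient_fields = as.integer(n_gradient_fields),
         use_gradients = use_gradients,
         use_array_effects = use_array_effects,
         array_effect_range = array_effect_range,
         sigma_error = sigma_error, off_fraction = off_fraction,
         pathway_mode = pathway_mode, bio_sd = bio_sd,
         tech_halfwidth = tech_halfwidth),
    class = "sim_config")
}

#' Smooth intraslide gradient field
#'
#' A low-spatial-frequency surface over the full logical grid (all sets
#' stacked): the sum of 1-3 random cosine waves and Gaussian bumps, rescaled
#' to mean zero and a max - min range equal to `strength` log2 units.
#'
#' @param strength Field range (max - min) in log2 units; 0 gives a zero
#'   field.
#' @param seed Integer seed; fields are deterministic per seed.
#' @param n_rows,n_cols Grid dimensions (default 96 x 32).
#' @return A numeric `n_rows` x `n_cols` matrix.
#' @export
generate_gradient_field <- function(strength, seed, n_rows = 96L,
                                    n_cols = 32L) {
  stopifnot(strength >= 0)
  if (strength == 0) return(matrix(0, n_rows, n_cols))
  f <- with_substream(seed, "gradient_field", {
    r <- (seq_len(n_rows) - 1) / max(n_rows - 1, 1)
    c <- (seq_len(n_cols) - 1) / max(n_cols - 1, 1)
    field <- matrix(0, n_rows, n_cols)
    for (b in seq_len(sample(1:3, 1))) {
      if (stats::runif(1) < 0.5) {
        fr <- stats::runif(1, 0.25, 1); fc <- stats::runif(1, 0.25, 1)
        ph <- stats::runif(1, 0, 2 * pi)
        field <- field + outer(r, c, function(y, x)
          cos(2 * pi * (fr * y + fc * x) + ph))
      } else {
        cy <- stats::runif(1); cx <- stats::runif(1)
        sy <- stats::runif(1, 0.2, 0.6); sx <- stats::runif(1, 0.2, 0.6)
        a <- sample(c(-1, 1), 1)
        field <- field + a * outer(r, c, function(y, x)
          exp(-((y - cy)^2 / (2 * sy^2) + (x - cx)^2 / (2 * sx^2))))
      }
    }
    field
  })
  rng <- diff(range(f))
  if (rng == 0) f[] <- 0 else {
    f <- f * (strength / rng)
    f <- f - mean(f)
    # recentre can shift extremes off-symmetric but preserves the range
  }
  f
}

#' Synthetic substrate -> kinase -> pathway annotation
#'
#' Builds the annotation table matching the simulated experiment: the induced
#' substrates are organized as 2 induced pathways of 9 kinases each (18
#' kinases in total, default 197 substrates split 11/10 per kinase), and the
#' remaining substrates are chunked into decoy pathways of comparable size
#' that contain no induced substrate.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (the induced substrate identities are drawn from
#'   the same substream as in [simulate_experiment()], so annotation and
#'   simulation agree).
#' @return A tibble with `substrate_id`, `kinase`, `pathway`, `induced`.
#' @export
annotation_fixture <- function(config, seed = 1L) {
  n_sub <- n_substrates(config$layout)
  induced <- draw_induced(config, seed)
  sizes <- chunk_sizes(length(induced), 18L)
  kin <- rep(sprintf("KIN%02d", seq_len(18L)), sizes)
  pw <- ifelse(kin %in% sprintf("KIN%02d", 1:9), "induced_1", "induced_2")
  ann <- tibble::tibble(substrate_id = induced,
                        kinase = as.character(kin),
                        pathway = as.character(pw),
                        induced = rep(TRUE, length(induced)))
  rest <- setdiff(seq_len(n_sub), induced)
  n_decoy_pw <- 8L
  per_pw <- 9L * 11L
  n_take <- min(length(rest), n_decoy_pw * per_pw)
  rest <- rest[seq_len(n_take)]
  if (n_take > 0) {
    pw_i <- (seq_len(n_take) - 1L) %/% per_pw + 1L
    kin_i <- (seq_len(n_take) - 1L) %/% 11L + 1L
    decoy <- tibble::tibble(
      substrate_id = rest,
      kinase = sprintf("DKIN%03d", kin_i),
      pathway = sprintf("decoy_%d", pw_i),
      induced = FALSE)
    ann <- dplyr::bind_rows(ann, decoy)
  }
  dplyr::arrange(ann, .data$substrate_id)
}

chunk_sizes <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

draw_induced <- function(config, seed) {
  n_sub <- n_substrates(config$layout)
  with_substream(seed, "induced",
                 sort(sample.int(n_sub, config$n_induced)))
}

#' Simulate a virtual control/treatment kinome profiling experiment
#'
#' Generates, for each virtual patient, a control and a treatment slide as
#' spot tables, together with the ground truth (induced substrates, realized
#' effects, injected gradients, array effects, off-spot labels). All
#' replicates of a substrate share its basic intensity, patient variation and
#' treatment effect, and differ by spot error and by the gradient value at
#' their own grid position. Fully reproducible given the master seed; each
#' variance component draws from a named substream, so altering one leaves
#' the others untouched.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return An object of class `virtual_experiment`: `spots` (one tibble over
#'   all slides), `truth`, `annotation`, `array_effects`, `gradient_fields`,
#'   `gradient_assignment`, `patient_bio_effects`, `tech_effects`, `config`,
#'   `seed`.
#' @export
simulate_experiment <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  n_sub <- n_substrates(layout)
  np <- config$n_patients
  ns <- layout$n_sets

  induced_ids <- draw_induced(config, seed)
  induced <- seq_len(n_sub) %in% induced_ids

  basic <- with_substream(seed, "basic",
    stats::rnorm(n_sub, config$mu_basic, config$sigma_basic))
  pat_var <- with_substream(seed, "patient",
    matrix(stats::rnorm(n_sub * np, 0, config$sigma_patient), n_sub, np))

  bio <- if (config$pathway_mode)
    with_substream(seed, "bio_effect", stats::rnorm(np, 0, config$bio_sd))
  else rep(0, np)
  tech <- if (config$pathway_mode)
    with_substream(seed, "tech_effect",
      stats::runif(n_sub, -config$tech_halfwidth, config$tech_halfwidth))
  else rep(0, n_sub)

  n_off <- round(config$off_fraction * n_sub)
  off_ids <- integer(0)
  if (n_off > 0) {
    pool <- setdiff(seq_len(n_sub), induced_ids)
    off_ids <- with_substream(seed, "offspots", {
      if (n_off <= length(pool)) sort(sample(pool, n_off))
      else sort(c(pool, sample(induced_ids, n_off - length(pool))))
    })
  }
  off <- seq_len(n_sub) %in% off_ids

  fields <- lapply(seq_len(config$n_gradient_fields), function(k)
    generate_gradient_field(
      if (config$use_gradients) config$gradient_strength else 0,
      substream_seed(seed, paste0("field", k)),
      n_rows = ns * layout$set_rows, n_cols = layout$set_cols))
  n_slides <- 2L * np
  pick <- with_substream(seed, "gradient_pick",
    sample.int(config$n_gradient_fields, n_slides, replace = TRUE))
  ae <- if (config$use_array_effects)
    with_substream(seed, "array",
      stats::runif(n_slides, config$array_effect_range[1],
                   config$array_effect_range[2]))
  else rep(0, n_slides)
  eps <- with_substream(seed, "error",
    array(stats::rnorm(n_sub * ns * n_slides, 0, config$sigma_error),
          dim = c(n_sub, ns, n_slides)))
  off_noise <- with_substream(seed, "off_noise",
    array(stats::rnorm(max(1, length(off_ids)) * ns * n_slides, 0,
                       config$sigma_error),
          dim = c(max(1, length(off_ids)), ns, n_slides)))

  base_tab <- new_spot_table(layout)
  pos_field_row <- base_tab$set * layout$set_rows + base_tab$row + 1L
  pos_field_col <- base_tab$col + 1L
  sub_idx <- base_tab$substrate_id
  set_idx <- base_tab$set + 1L

  slides <- vector("list", n_slides)
  meta <- tibble::tibble(
    patient = rep(seq_len(np), each = 2L),
    condition = rep(c("control", "treatment"), np))
  meta$slide <- seq_len(n_slides)
  for (k in seq_len(n_slides)) {
    pt <- meta$patient[k]; cond <- meta$condition[k]
    level <- basic + pat_var[, pt]
    if (cond == "treatment") {
      eff <- config$effect_size + bio[pt] + tech
      level <- level + ifelse(induced, eff, 0)
    }
    g <- fields[[pick[k]]]
    v <- level[sub_idx] + g[cbind(pos_field_row, pos_field_col)] + ae[k] +
      eps[cbind(sub_idx, set_idx, k)]
    tab <- base_tab
    tab$slide_id <- sprintf("p%02d_%s", pt, cond)
    tab$condition <- cond
    tab$net_log2 <- v
    if (length(off_ids) > 0) {
      is_off <- sub_idx %in% off_ids
      oi <- match(sub_idx[is_off], off_ids)
      tab$net_log2[is_off] <- off_noise[cbind(oi, set_idx[is_off], k)]
      tab$ks[is_off] <- 1L
      tab$overall[is_off] <- 1L
    }
    tab$patient <- pt
    slides[[k]] <- tab
  }

  realized <- outer(tech, bio, "+") + config$effect_size  # n_sub x np
  realized[!induced, ] <- 0
  out <- list(
    spots = dplyr::bind_rows(slides),
    truth = tibble::tibble(substrate_id = seq_len(n_sub),
                           induced = induced, off = off),
    annotation = annotation_fixture(config, seed),
    array_effects = tibble::tibble(patient = meta$patient,
                                   condition = meta$condition,
                                   array_effect = ae),
    gradient_fields = fields,
    gradient_assignment = tibble::tibble(patient = meta$patient,
                                         condition = meta$condition,
                                         field = pick),
    patient_bio_effects = tibble::tibble(patient = seq_len(np), bio = bio),
    tech_effects = tibble::tibble(substrate_id = seq_len(n_sub), tech = tech),
    realized_effects = realized,
    config = config, seed = as.integer(seed))
  class(out) <- "virtual_experiment"
  out
}

#' @export
print.virtual_experiment <- function(x, ...) {
  cat(sprintf(
    "<virtual_experiment> %d patient(s) x 2 conditions, %d substrates (%d induced, %d off)\n",
    x$config$n_patients, nrow(x$truth), sum(x$truth$induced),
    sum(x$truth$off)))
  cat(sprintf("  effect size %.2f log2, gradients %s, array effects %s, seed %d\n",
              x$config$effect_size,
              if (x$config$use_gradients) sprintf("on (%.2f)", x$config$gradient_strength) else "off",
              if (x$config$use_array_effects) "on" else "off", x$seed))
  invisible(x)
}

#' Extract one slide of a virtual experiment
#'
#' @param exper A [simulate_experiment()] result.
#' @param patient Patient number.
#' @param condition `"control"` or `"treatment"`.
#' @return The slide's spot table.
#' @export
experiment_slide <- function(exper, patient, condition) {
  dplyr::filter(exper$spots, .data$patient == !!patient,
                .data$condition == !!condition)
}
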