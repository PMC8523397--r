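#' Generate a synthetic study cohort
#'
#' Produces one row per knee with covariates, stratified outcome labels, a
#' stratified segmentation-QC flag, and a per-subject phantom seed. Label
#' assignment is stratified (exactly `round(n * prevalence)` positives), not
#' Bernoulli, so that downstream checks on prevalence are exact. Covariates
#' are drawn from the cohort's reference normals (age mean 54.6, SD 3.7
#' years; BMI mean 26.8, SD 4.6 kg/m^2) and are independent of the labels by
#' default, so covariate-only models are near chance on synthetic data; an
#' association switch can shift the covariates of positive knees.
#'
#' @param n number of knees (>= 10).
#' @param prevalence tibiofemoral OA prevalence in (0, 1); default 76/665.
#' @param params a [phantom_params()] object (stored for downstream stages).
#' @param seed integer seed.
#' @param sub_prevalence named fractions for the three medial tibial
#'   sub-outcomes (cartilage damage, osteophyte, BML).
#' @param correction_rate fraction of knees flagged as needing manual
#'   segmentation correction (QC emulation only).
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate distribution parameters.
#' @param covariate_label_assoc logical; if `TRUE`, positive knees get a
#'   +0.8 SD shift in age and BMI.
#' @return a `CohortTable` tibble.
#' @export
generate_cohort <- function(n, prevalence = 76 / 665,
                            params = phantom_params(), seed = 1L,
                            sub_prevalence = c(cartilage = 91 / 665,
                                               osteophyte = 85 / 665,
                                               bml = 70 / 665),
                            correction_rate = 86 / 665,
                            age_mean = 54.6, age_sd = 3.7,
                            bmi_mean = 26.8, bmi_sd = 4.6,
                            covariate_label_assoc = FALSE) {
  stopifnot(n >= 10, prevalence > 0, prevalence < 1)
  if (n * prevalence < 1) stop("n * prevalence < 1: no positive knees possible")
  with_local_seed(seed, {
    strat <- function(p) sample(rep(c(TRUE, FALSE), c(round(n * p), n - round(n * p))))
    label_tfoa <- strat(prevalence)
    label_cartilage <- strat(sub_prevalence[["cartilage"]])
    label_osteophyte <- strat(sub_prevalence[["osteophyte"]])
    label_bml <- strat(sub_prevalence[["bml"]])
    needs_correction <- strat(correction_rate)
    age <- rnorm(n, age_mean, age_sd)
    bmi <- rnorm(n, bmi_mean, bmi_sd)
    if (covariate_label_assoc) {
      age <- age + 0.8 * age_sd * label_tfoa
      bmi <- bmi + 0.8 * bmi_sd * label_tfoa
    }
    age <- pmax(age, 18)
    bmi <- pmax(bmi, 12)
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, bmi = bmi,
      label_tfoa = label_tfoa,
      label_cartilage = label_cartilage,
      label_osteophyte = label_osteophyte,
      label_bml = label_bml,
      needs_correction = needs_correction,
      phantom_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
}

#' Sample MOAKS records consistent with requested labels
#'
#' Inverse sampling of the rule-based MOAKS definitions: the returned
#' records, passed back through [classify_tibiofemoral_oa()] and the medial
#' sub-outcome classifiers, reproduce the requested labels exactly. Positive
#' tibiofemoral OA knees are realised through a randomly chosen route (both
#' primary features, or one primary plus two secondary features) placed at
#' femoral/lateral sites so the medial tibial sub-labels stay independent.
#'
#' @param labels a data frame (e.g. a [generate_cohort()] table) with logical
#'   columns `label_tfoa`, `label_cartilage`, `label_osteophyte`, `label_bml`;
#'   or a named logical list for a single knee.
#' @param seed integer seed.
#' @return a MOAKS tibble, one row per knee (with `subject_id` if present in
#'   `labels`).
#' @export
generate_moaks_record <- function(labels, seed = 1L) {
  if (!is.data.frame(labels)) labels <- tibble::as_tibble(as.list(labels))
  need <- c("label_tfoa", "label_cartilage", "label_osteophyte", "label_bml")
  missing <- setdiff(need, names(labels))
  if (length(missing) > 0) stop("labels missing: ", paste(missing, collapse = ", "))
  n <- nrow(labels)
  m <- tibble::tibble(
    cart_med_tib_ant = integer(n), cart_med_tib_cen = integer(n),
    cart_med_tib_pos = integer(n), cart_lat_tib = integer(n),
    cart_med_fem = integer(n), cart_lat_fem = integer(n),
    ost_med_tib = integer(n), ost_lat_tib = integer(n),
    ost_med_fem = integer(n), ost_lat_fem = integer(n),
    bml_med_tib_ant = integer(n), bml_med_tib_cen = integer(n),
    bml_med_tib_pos = integer(n), bml_lat_tib = integer(n),
    cyst_grade = integer(n),
    bml_cyst_nonattachment = logical(n),
    meniscus_degen_grade = integer(n),
    meniscus_horizontal_tear = logical(n))

  with_local_seed(seed, {
    for (i in seq_len(n)) {
      tfoa <- isTRUE(labels$label_tfoa[i])
      # medial tibial sub-outcomes, chosen so they never create a primary
      # feature on their own (cartilage kept partial, osteophyte grade 1
      # unless the knee is OA anyway)
      if (isTRUE(labels$label_cartilage[i])) {
        site <- sample(c("cart_med_tib_ant", "cart_med_tib_cen",
                         "cart_med_tib_pos"), 1)
        m[[site]][i] <- sample(1:2, 1)
      }
      if (isTRUE(labels$label_osteophyte[i])) {
        m$ost_med_tib[i] <- if (tfoa) sample(1:3, 1) else 1L
      }
      if (isTRUE(labels$label_bml[i])) {
        site <- sample(c("bml_med_tib_ant", "bml_med_tib_cen",
                         "bml_med_tib_pos"), 1)
        m[[site]][i] <- sample(1:3, 1)
      }
      if (tfoa) {
        route <- sample(c("both", "ost_plus2", "cart_plus2"), 1)
        if (route == "both") {
          m$ost_lat_fem[i] <- sample(2:3, 1)
          m$cart_lat_fem[i] <- 3L
        } else {
          if (route == "ost_plus2") m$ost_lat_fem[i] <- sample(2:3, 1)
          else m$cart_lat_fem[i] <- 3L
          secs <- sample(c("bmlcyst", "meniscus", "partial"), 2)
          if ("bmlcyst" %in% secs) {
            m$cyst_grade[i] <- sample(1:3, 1)
            m$bml_cyst_nonattachment[i] <- TRUE
          }
          if ("meniscus" %in% secs) {
            if (runif(1) < 0.5) m$meniscus_degen_grade[i] <- sample(1:3, 1)
            else m$meniscus_horizontal_tear[i] <- TRUE
          }
          if ("partial" %in% secs) {
            m$cart_med_fem[i] <- sample(1:2, 1)
          }
        }
      }
    }
    NULL
  })

  if ("subject_id" %in% names(labels)) {
    m <- dplyr::bind_cols(tibble::tibble(subject_id = labels$subject_id), m)
  }
  # round-trip guarantee: the sampled records must reproduce the labels
  ok <- identical(unname(classify_tibiofemoral_oa(m)),
                  unname(as.logical(labels$label_tfoa))) &&
    identical(unname(label_medial_cartilage_damage(m)),
              unname(as.logical(labels$label_cartilage))) &&
    identical(unname(label_medial_osteophyte(m)),
              unname(as.logical(labels$label_osteophyte))) &&
    identical(unname(label_medial_bml(m)),
              unname(as.logical(labels$label_bml)))
  if (!ok) stop("internal error: sampled MOAKS records do not round-trip the labels")
  m
}
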