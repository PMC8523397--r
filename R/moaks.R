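#' Rule-based MOAKS osteoarthritis definitions
#'
#' A MOAKS record is one row per knee with ordinal grades (0-3) per
#' site-feature: cartilage loss (`cart_*`: medial tibia anterior / central /
#' posterior, lateral tibia, medial and lateral femur), osteophytes (`ost_*`:
#' medial and lateral tibia and femur), bone marrow lesions (`bml_*`: medial
#' tibia anterior / central / posterior, lateral tibia), a cyst grade, a flag
#' for BML/cyst not associated with meniscal or ligamentous attachments, a
#' meniscal maceration/degeneration grade, and a horizontal-tear flag.
#'
#' Tibiofemoral osteoarthritis is positive when both primary features
#' (a definite osteophyte, i.e. any osteophyte grade 2-3, and full-thickness
#' cartilage loss, i.e. any cartilage grade 3) are present, or when one
#' primary is present together with at least two of three secondary features:
#' (1) a BML or cyst of grade >= 1 not associated with attachments,
#' (2) meniscal maceration/degeneration grade >= 1 or a horizontal tear,
#' (3) partial-thickness cartilage loss (any cartilage grade 1-2).
#'
#' @param moaks a MOAKS tibble (one row per knee) as produced by
#'   [generate_moaks_record()], or a single-row list with the same names.
#' @param tibia_only logical; restrict the two primary features to tibial
#'   sites (default `FALSE`: any tibiofemoral site counts, the knee-level
#'   pooling used for the headline outcome).
#' @return logical vector, one element per knee.
#' @export
classify_tibiofemoral_oa <- function(moaks, tibia_only = FALSE) {
  m <- as_moaks_frame(moaks)
  ost_sites <- if (tibia_only) c("ost_med_tib", "ost_lat_tib") else
    c("ost_med_tib", "ost_lat_tib", "ost_med_fem", "ost_lat_fem")
  cart_sites_primary <- if (tibia_only) {
    c("cart_med_tib_ant", "cart_med_tib_cen", "cart_med_tib_pos", "cart_lat_tib")
  } else {
    c("cart_med_tib_ant", "cart_med_tib_cen", "cart_med_tib_pos",
      "cart_lat_tib", "cart_med_fem", "cart_lat_fem")
  }
  cart_all <- c("cart_med_tib_ant", "cart_med_tib_cen", "cart_med_tib_pos",
                "cart_lat_tib", "cart_med_fem", "cart_lat_fem")
  bml_sites <- c("bml_med_tib_ant", "bml_med_tib_cen", "bml_med_tib_pos",
                 "bml_lat_tib")

  p1 <- row_any(m, ost_sites, function(g) g >= 2)        # definite osteophyte
  p2 <- row_any(m, cart_sites_primary, function(g) g == 3)  # full thickness
  partial <- row_any(m, cart_all, function(g) g %in% c(1, 2))
  bml_cyst <- (row_any(m, bml_sites, function(g) g >= 1) | m$cyst_grade >= 1) &
    as.logical(m$bml_cyst_nonattachment)
  meniscus <- m$meniscus_degen_grade >= 1 | as.logical(m$meniscus_horizontal_tear)
  secondaries <- bml_cyst + meniscus + partial
  (p1 & p2) | ((p1 | p2) & secondaries >= 2)
}

#' @rdname classify_tibiofemoral_oa
#' @export
label_medial_cartilage_damage <- function(moaks) {
  m <- as_moaks_frame(moaks)
  row_any(m, c("cart_med_tib_ant", "cart_med_tib_cen", "cart_med_tib_pos"),
          function(g) g >= 1)
}

#' @rdname classify_tibiofemoral_oa
#' @export
label_medial_osteophyte <- function(moaks) {
  m <- as_moaks_frame(moaks)
  row_any(m, "ost_med_tib", function(g) g >= 1)
}

#' @rdname classify_tibiofemoral_oa
#' @export
label_medial_bml <- function(moaks) {
  m <- as_moaks_frame(moaks)
  row_any(m, c("bml_med_tib_ant", "bml_med_tib_cen", "bml_med_tib_pos"),
          function(g) g >= 1)
}

#' Append the four rule-based labels to a MOAKS table
#'
#' @param moaks MOAKS tibble.
#' @param tibia_only passed to [classify_tibiofemoral_oa()].
#' @return the input tibble with boolean columns `label_tfoa`,
#'   `label_cartilage`, `label_osteophyte`, `label_bml` appended.
#' @export
moaks_label_table <- function(moaks, tibia_only = FALSE) {
  dplyr::mutate(tibble::as_tibble(moaks),
                label_tfoa = classify_tibiofemoral_oa(moaks, tibia_only),
                label_cartilage = label_medial_cartilage_damage(moaks),
                label_osteophyte = label_medial_osteophyte(moaks),
                label_bml = label_medial_bml(moaks))
}

moaks_grade_cols <- function() {
  c("cart_med_tib_ant", "cart_med_tib_cen", "cart_med_tib_pos",
    "cart_lat_tib", "cart_med_fem", "cart_lat_fem",
    "ost_med_tib", "ost_lat_tib", "ost_med_fem", "ost_lat_fem",
    "bml_med_tib_ant", "bml_med_tib_cen", "bml_med_tib_pos", "bml_lat_tib",
    "cyst_grade", "meniscus_degen_grade")
}

as_moaks_frame <- function(moaks) {
  m <- if (is.data.frame(moaks)) tibble::as_tibble(moaks)
       else tibble::as_tibble(as.list(moaks))
  needed <- c(moaks_grade_cols(), "bml_cyst_nonattachment",
              "meniscus_horizontal_tear")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    stop("MOAKS record is missing columns: ", paste(missing, collapse = ", "))
  }
  for (cn in moaks_grade_cols()) {
    g <- m[[cn]]
    if (any(!is.finite(g)) || any(g != as.integer(g)) || any(g < 0 | g > 3)) {
      stop(sprintf("grade out of range 0..3 in column '%s'", cn))
    }
  }
  m
}

row_any <- function(m, cols, pred) {
  out <- rep(FALSE, nrow(m))
  for (cn in cols) out <- out | pred(m[[cn]])
  out
}
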