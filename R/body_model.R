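# Canonical segment order (i = 1..12) and layer order (j = 1..4).
.segments <- c("head", "shoulder", "chest", "abdomen", "upper_arm", "lower_arm",
               "hand", "l_thigh", "r_thigh", "l_calf", "r_calf", "feet")
.layers <- c("core", "equivalent", "skin", "clothing")

# Tissue constants shared by all segments (layer-wise conductivity, specific
# heat and density for the core and skin layers; the equivalent layer carries
# per-segment values from the parameter table).
.tissue <- list(
  k_core = 0.5,    # W/(m K), deep tissue
  k_skin = 0.3,    # W/(m K)
  c_core = 3500,   # J/(kg K)
  c_skin = 3680,   # J/(kg K)
  rho_core = 1050, # kg/m^3
  rho_eq = 1000,
  rho_skin = 1085,
  rho_clothing = 300
)

#' Segment names of the body model
#'
#' The twelve anatomical segments, in canonical order: head, shoulder, chest,
#' abdomen, upper arm, lower arm, hand, left/right thigh, left/right calf,
#' feet. All per-segment vectors and matrices in the package follow this
#' order.
#'
#' @return Character vector of length 12.
#' @export
body_segments <- function() .segments

#' Default thermoregulatory control coefficients
#'
#' Gains of the hypothalamic controller (vasodilation `Cdl`/`Sdl`/`Pdl`,
#' vasoconstriction `Cst`/`Sst`/`Pst`), the local Q10 sensitivity scale `RT`
#' (degrees C), the shivering gain, the countercurrent heat-transfer ratio
#' `a`, the volumetric heat capacity of blood `rho_b` (W h / (L K)) and the
#' central blood-pool heat capacity `Cp_b` (J/K). Values follow the multi-node
#' thermophysiology literature this model family descends from; every one can
#' be overridden through the scenario configuration `control:` block.
#'
#' @param ... Named overrides of individual coefficients.
#' @return Named list of control coefficients.
#' @export
default_control <- function(...) {
  ctl <- list(
    Cdl = 117, Sdl = 7.5, Pdl = 0,
    Cst = 5, Sst = 0.5, Pst = 0,
    RT = 10,
    shiver_gain = 24.36,
    a = 1.0,
    rho_b = 1.067,   # W h / (L K); 3841.2 J/(L K)
    Cp_b = 9600      # J/K, ~2.5 L central pool
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(ctl))
    if (length(bad)) stop("unknown control coefficient(s): ", paste(bad, collapse = ", "))
    ctl[names(over)] <- over
  }
  stopifnot(ctl$RT > 0, ctl$rho_b > 0, ctl$a > 0, ctl$a <= 1, ctl$Cp_b > 0)
  ctl
}

.body_columns <- c("segment", "area", "d_core", "d_eq", "d_skin", "k_eq", "c_eq",
                   "Q0_core", "Q0_eq", "Q0_skin",
                   "Tset_core", "Tset_eq", "Tset_skin",
                   "Bb_core", "Bb_eq", "Bb_skin",
                   "SKINR", "SKINV", "SKINC", "Metf", "hc_shape")

.read_body_table <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("body parameter file not found: ", x)
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop("body table must be a data frame or a path to a TSV file")
  miss <- setdiff(.body_columns, names(x))
  if (length(miss)) stop("body table is missing column(s): ", paste(miss, collapse = ", "))
  x[, .body_columns]
}

.default_body_path <- function() {
  system.file("extdata", "body_default.tsv", package = "coldtherm", mustWork = TRUE)
}

.validate_body_table <- function(seg) {
  if (!setequal(seg$segment, .segments) || anyDuplicated(seg$segment))
    stop("configuration error: body table must contain each of the 12 segments exactly once")
  seg <- seg[match(.segments, seg$segment), ]
  num_cols <- setdiff(.body_columns, "segment")
  for (col in num_cols) {
    v <- seg[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("configuration error: non-numeric or missing value in field '", col,
           "' (segment ", seg$segment[which(!is.finite(v))[1]], ")")
  }
  if (any(seg$area <= 0))
    stop("configuration error: field 'area' must be > 0 (segment ",
         seg$segment[which(seg$area <= 0)[1]], ")")
  nonneg <- c("k_eq", "c_eq", "Q0_core", "Q0_eq", "Q0_skin",
              "Bb_core", "Bb_eq", "Bb_skin", "SKINR", "SKINV", "SKINC", "Metf")
  for (col in nonneg) {
    if (any(seg[[col]] < 0))
      stop("configuration error: field '", col, "' must be >= 0 (segment ",
           seg$segment[which(seg[[col]] < 0)[1]], ")")
  }
  if (any(seg[, c("d_core", "d_eq", "d_skin")] <= 0))
    stop("configuration error: layer thicknesses must be > 0")
  for (w in c("SKINR", "Metf")) {
    s <- sum(seg[[w]])
    if (abs(s - 1) > 1e-6)
      stop("validation error: ", w, " weights must sum to 1 (got ", format(s), ")")
  }
  seg
}

#' Build the segmented body model
#'
#' Assembles and validates the 12-segment, 4-layer body description: skin
#' areas, layer thicknesses, thermophysical properties, basal metabolic heats
#' `Q0`, set-point temperatures, basal blood flows `Bb`, the skin-sensor
#' weights `SKINR`, the vasomotor distribution weights `SKINV`/`SKINC`, the
#' work/shiver distribution `Metf`, and the inter-layer conductances derived
#' from geometry. Heat capacities per tissue node are `rho * c * A * d`;
#' conductances between adjacent layer centres are series half-thickness
#' resistances (the core additionally conducts to the 37 degree core wall
#' through its inner half-thickness).
#'
#' @param config `NULL` for the packaged defaults; a path to a YAML scenario
#'   file; or a list with optional entries `body` (data frame or TSV path with
#'   one row per segment, columns as in the packaged
#'   `extdata/body_default.tsv`) and `control` (named overrides of
#'   [default_control()] coefficients).
#' @return An object of class `body_model`: list with `segments` (the
#'   validated parameter table), `control`, `total_area` (m^2), matrices
#'   `Q0`, `Tset`, `Bb`, `Cp` (12 x 3, layers core/equivalent/skin) and
#'   conductance vectors `K0` (core wall to core), `K12`, `K23` (W/K).
#' @export
build_body <- function(config = NULL) {
  if (is.character(config)) config <- load_scenario(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))

  body <- config$body
  if (is.null(body) || identical(body, "default")) body <- .default_body_path()
  seg <- .validate_body_table(.read_body_table(body))

  ctl <- do.call(default_control, as.list(config$control))

  A <- seg$area
  # node heat capacities, J/K
  Cp <- cbind(
    core = .tissue$rho_core * .tissue$c_core * A * seg$d_core,
    equivalent = .tissue$rho_eq * seg$c_eq * A * seg$d_eq,
    skin = .tissue$rho_skin * .tissue$c_skin * A * seg$d_skin
  )
  # conductances between node centres (slab approximation), W/K
  K0 <- .tissue$k_core * A / (0.5 * seg$d_core)
  K12 <- A / (0.5 * seg$d_core / .tissue$k_core + 0.5 * seg$d_eq / seg$k_eq)
  K23 <- A / (0.5 * seg$d_eq / seg$k_eq + 0.5 * seg$d_skin / .tissue$k_skin)

  mk <- function(cols) {
    m <- as.matrix(seg[, cols])
    dimnames(m) <- list(seg$segment, c("core", "equivalent", "skin"))
    m
  }
  model <- structure(list(
    segments = seg,
    control = ctl,
    total_area = sum(A),
    Q0 = mk(c("Q0_core", "Q0_eq", "Q0_skin")),
    Tset = mk(c("Tset_core", "Tset_eq", "Tset_skin")),
    Bb = mk(c("Bb_core", "Bb_eq", "Bb_skin")),
    Cp = structure(Cp, dimnames = list(seg$segment, c("core", "equivalent", "skin"))),
    K0 = stats::setNames(K0, seg$segment),
    K12 = stats::setNames(K12, seg$segment),
    K23 = stats::setNames(K23, seg$segment)
  ), class = "body_model")
  stopifnot(abs(model$total_area - sum(model$segments$area)) <= 1e-3 * model$total_area)
  model
}

#' Area fraction of each body segment
#'
#' @param model A [build_body()] model.
#' @return Named vector of fractions (sums to 1).
#' @export
segment_area_fractions <- function(model) {
  stopifnot(inherits(model, "body_model"))
  f <- model$segments$area / model$total_area
  stats::setNames(f, model$segments$segment)
}

#' Serialize a body model's parameter table
#'
#' Writes the per-segment parameter table as tab-separated text, in the same
#' layout as the packaged default; `build_body(list(body = path))` rebuilds an
#' identical model.
#'
#' @param model A `body_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_body <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  utils::write.table(model$segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a scenario configuration file
#'
#' Scenario files are YAML with optional blocks `body` (path to a body
#' parameter TSV or the string `"default"`), `control` (named coefficient
#' overrides), `clothing` (`"winter"`, `"summer"` or a TSV path), `fcl`,
#' `environment` (`Ta` in degrees C, `RH` as a fraction) and `options`
#' (forwarded to [simulate_body()]).
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  yaml::read_yaml(path)
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model> 12 segments, total skin area",
      format(x$total_area, digits = 4), "m^2\n")
  cat("  basal metabolic heat:", format(sum(x$Q0), digits = 4), "W;",
      "basal blood flow:", format(sum(x$Bb), digits = 4), "L/h\n")
  invisible(x)
}
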