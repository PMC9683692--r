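#' Default parameter table of the packaged cardiovascular model
#'
#' Returns the full physiological parameter configuration of the packaged
#' closed-loop lumped-parameter cardiovascular system model: the 12 candidate
#' fitting parameters (status `"free"`) together with all fixed physiological
#' constants (valve resistances, segment resistances and compliances, chamber
#' baseline elastances and unstressed volumes, activation timing, venous
#' return resistances, and the heart period).
#'
#' Units follow the SI-derived convention used throughout the package:
#' volumes in m^3, pressures in MPa, resistances in MPa.s/m^3, compliances
#' in m^3/MPa, elastances in MPa/m^3, times in s. Pressures in reported
#' observables are expressed in kPa.
#'
#' The 12 candidate fitting parameters are: the stressed blood volume
#' `q_sbv`, the maximum left and right ventricular elastances `E_LVa` and
#' `E_RVa`, the pulmonary arterial resistance `R_par`, the seven terminal
#' bed resistances `R_LE_T`, `R_BR_T`, `R_AC_T`, `R_EC_T`, `R_MC_T`,
#' `R_PC_T`, `R_TR_T`, and the total venous compliance `C_V`.
#'
#' @return A tibble with columns `name`, `units`, `value`, `min`, `max`,
#'   `status` (`"free"` or `"fixed"`). `value` lies within `[min, max]` for
#'   every row.
#' @export
#' @examples
#' pt <- cvs_parameters()
#' subset(pt, status == "free")
cvs_parameters <- function() {
  if (is.null(.cvs_cache$ptable)) .cvs_cache$ptable <- cvs_parameters_build()
  .cvs_cache$ptable
}

.cvs_cache <- new.env(parent = emptyenv())

cvs_parameters_build <- function() {
  tibble::tribble(
    ~name,        ~units,       ~value,  ~min,    ~max,    ~status,
    # candidate fitting parameters
    "q_sbv",      "m3",         1.0e-3,  4e-4,    2.5e-3,  "free",
    "E_LVa",      "MPa/m3",     300,     80,      900,     "free",
    "E_RVa",      "MPa/m3",     73.3,    20,      300,     "free",
    "R_par",      "MPa.s/m3",   10.7,    2,       60,      "free",
    "R_LE_T",     "MPa.s/m3",   1200,    300,     8000,    "free",
    "R_BR_T",     "MPa.s/m3",   3500,    800,     20000,   "free",
    "R_AC_T",     "MPa.s/m3",   7000,    1500,    40000,   "free",
    "R_EC_T",     "MPa.s/m3",   4200,    1000,    25000,   "free",
    "R_MC_T",     "MPa.s/m3",   4500,    1000,    25000,   "free",
    "R_PC_T",     "MPa.s/m3",   19000,   4000,    80000,   "free",
    "R_TR_T",     "MPa.s/m3",   200,     50,      2000,    "free",
    "C_V",        "m3/MPa",     0.5,     0.1,     2.5,     "free",
    # heart chambers: baseline elastances, unstressed volumes, activation
    "E_LVb",      "MPa/m3",     8,       1,       30,      "fixed",
    "q_LV_un",    "m3",         1.0e-5,  0,       5e-5,    "fixed",
    "on_LV",      "fraction",   0.0,     0,       1,       "fixed",
    "du_LV",      "fraction",   0.30,    0.05,    0.6,     "fixed",
    "E_RVb",      "MPa/m3",     4,       1,       30,      "fixed",
    "q_RV_un",    "m3",         1.0e-5,  0,       5e-5,    "fixed",
    "on_RV",      "fraction",   0.0,     0,       1,       "fixed",
    "du_RV",      "fraction",   0.30,    0.05,    0.6,     "fixed",
    "E_LAa",      "MPa/m3",     36,      5,       150,     "fixed",
    "E_LAb",      "MPa/m3",     12,      2,       60,      "fixed",
    "q_LA_un",    "m3",         5.0e-6,  0,       5e-5,    "fixed",
    "on_LA",      "fraction",   0.80,    0,       1,       "fixed",
    "du_LA",      "fraction",   0.17,    0.05,    0.5,     "fixed",
    "E_RAa",      "MPa/m3",     30,      5,       150,     "fixed",
    "E_RAb",      "MPa/m3",     10,      2,       60,      "fixed",
    "q_RA_un",    "m3",         5.0e-6,  0,       5e-5,    "fixed",
    "on_RA",      "fraction",   0.80,    0,       1,       "fixed",
    "du_RA",      "fraction",   0.17,    0.05,    0.5,     "fixed",
    # valves
    "R_trv",      "MPa.s/m3",   0.3,     0.05,    5,       "fixed",
    "R_puv",      "MPa.s/m3",   0.6,     0.05,    5,       "fixed",
    "R_miv",      "MPa.s/m3",   0.3,     0.05,    5,       "fixed",
    "R_aov",      "MPa.s/m3",   0.8,     0.05,    5,       "fixed",
    "k_valve",    "1/MPa",      3e4,     1e3,     1e6,     "fixed",
    # pulmonary circulation
    "C_par",      "m3/MPa",     0.03,    0.005,   0.2,     "fixed",
    "C_pvn",      "m3/MPa",     0.15,    0.02,    1,       "fixed",
    "R_pvn",      "MPa.s/m3",   0.5,     0.05,    5,       "fixed",
    # systemic arteries
    "C_AO",       "m3/MPa",     0.0113,  0.002,   0.1,     "fixed",
    "C_CER",      "m3/MPa",     0.002,   2e-4,    0.02,    "fixed",
    "R_seg_CER",  "MPa.s/m3",   30,      5,       200,     "fixed",
    "R_seg_BR",   "MPa.s/m3",   50,      5,       300,     "fixed",
    "R_seg_LE",   "MPa.s/m3",   30,      5,       300,     "fixed",
    "R_seg_TR",   "MPa.s/m3",   10,      2,       100,     "fixed",
    # terminal bed compliances and venous return resistances
    "C_LE_T",     "m3/MPa",     5.0e-4,  5e-5,    5e-3,    "fixed",
    "C_BR_T",     "m3/MPa",     2.0e-4,  2e-5,    2e-3,    "fixed",
    "C_AC_T",     "m3/MPa",     1.0e-4,  1e-5,    1e-3,    "fixed",
    "C_EC_T",     "m3/MPa",     1.5e-4,  1.5e-5,  1.5e-3,  "fixed",
    "C_MC_T",     "m3/MPa",     1.5e-4,  1.5e-5,  1.5e-3,  "fixed",
    "C_PC_T",     "m3/MPa",     5.0e-5,  5e-6,    5e-4,    "fixed",
    "C_TR_T",     "m3/MPa",     1.0e-3,  1e-4,    1e-2,    "fixed",
    "R_LE_V",     "MPa.s/m3",   120,     10,      1000,    "fixed",
    "R_BR_V",     "MPa.s/m3",   350,     10,      3000,    "fixed",
    "R_AC_V",     "MPa.s/m3",   700,     10,      6000,    "fixed",
    "R_EC_V",     "MPa.s/m3",   420,     10,      4000,    "fixed",
    "R_MC_V",     "MPa.s/m3",   450,     10,      4000,    "fixed",
    "R_PC_V",     "MPa.s/m3",   1900,    10,      16000,   "fixed",
    "R_TR_V",     "MPa.s/m3",   20,      2,       200,     "fixed",
    # veins
    "f_vub",      "fraction",   0.3,     0.05,    0.95,    "fixed",
    "R_svc",      "MPa.s/m3",   1.0,     0.1,     10,      "fixed",
    "R_ivc",      "MPa.s/m3",   0.8,     0.1,     10,      "fixed",
    # timing
    "period",     "s",          1.0,     0.3,     2,       "fixed"
  )
}

#' Names of the 12 candidate fitting parameters
#' @return Character vector of the free parameters in the default table.
#' @export
cvs_free_parameters <- function() {
  pt <- cvs_parameters()
  pt$name[pt$status == "free"]
}

#' Merge named parameter values into a parameter table
#'
#' @param ptable A parameter table as returned by [cvs_parameters()].
#' @param values Named numeric vector; names must exist in `ptable`.
#' @return The table with `value` replaced for the named entries.
#' @export
set_parameters <- function(ptable, values) {
  if (length(values) == 0) return(ptable)
  stopifnot(!is.null(names(values)))
  unknown <- setdiff(names(values), ptable$name)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  idx <- match(names(values), ptable$name)
  ptable$value[idx] <- unname(values)
  ptable
}

#' Read / write a parameter configuration CSV
#'
#' The CSV has header `name,units,value,min,max,status`.
#'
#' @param path File path.
#' @return `read_parameter_csv()` returns a parameter tibble.
#' @export
read_parameter_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "units", "value", "min", "max", "status")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(df[, need])
  validate_parameter_table(out)
  out
}

#' @rdname read_parameter_csv
#' @param ptable Parameter table to write.
#' @export
write_parameter_csv <- function(ptable, path) {
  utils::write.csv(ptable, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_parameter_table <- function(ptable) {
  stopifnot(all(is.finite(ptable$value)), all(is.finite(ptable$min)),
            all(is.finite(ptable$max)))
  if (anyDuplicated(ptable$name)) stop("duplicate parameter names")
  if (!all(ptable$status %in% c("free", "fixed"))) {
    stop("status must be 'free' or 'fixed'")
  }
  bad <- ptable$name[ptable$value < ptable$min | ptable$value > ptable$max]
  if (length(bad) > 0) {
    stop("parameter value outside [min, max]: ", paste(bad, collapse = ", "))
  }
  if (any(ptable$value < 0)) stop("parameter values must be non-negative")
  invisible(ptable)
}

# order must match the #define block in src/cvs_rhs.c; the last four
# entries are C_vub, C_vlb (split of C_V by f_vub), R_svc, R_ivc
cvs_parm_source_names <- function() {
  chamber <- function(ch) {
    c(paste0("E_", ch, "a"), paste0("E_", ch, "b"),
      paste0("q_", ch, "_un"), paste0("on_", ch), paste0("du_", ch))
  }
  c("period", "k_valve",
    chamber("LV"), chamber("RV"), chamber("LA"), chamber("RA"),
    "R_trv", "R_puv", "R_miv", "R_aov",
    "C_par", "R_par", "C_pvn", "R_pvn", "C_AO", "C_CER", "R_seg_CER",
    "R_seg_BR", "R_seg_LE", "R_seg_TR",
    as.vector(rbind(paste0("R_", cvs_terminal_beds(), "_T"),
                    paste0("C_", cvs_terminal_beds(), "_T"),
                    paste0("R_", cvs_terminal_beds(), "_V"))),
    "C_V", "C_V", "R_svc", "R_ivc")
}

cvs_model_parm_vector <- function(ptable) {
  cvs_parm_from_values(stats::setNames(ptable$value, ptable$name))
}

cvs_parm_from_values <- function(v) {
  src <- .cvs_cache$parm_src
  if (is.null(src)) src <- .cvs_cache$parm_src <- cvs_parm_source_names()
  p <- unname(v[match(src, names(v))])
  n <- length(p)
  f <- v[["f_vub"]]
  p[n - 3L] <- f * p[n - 3L]          # C_vub
  p[n - 2L] <- (1 - f) * p[n - 2L]    # C_vlb
  p
}

cvs_terminal_beds <- function() c("LE", "BR", "AC", "EC", "MC", "PC", "TR")
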