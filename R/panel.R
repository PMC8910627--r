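#' Construct a prevalence panel
#'
#' A prevalence panel holds one gender's unbalanced country-by-wave matrix of
#' prevalence percentages. Cells are `NA` where a country did not take part in
#' a survey wave; `NA` is never conflated with a prevalence of zero.
#'
#' @param values numeric matrix, countries in rows and waves in columns, with
#'   `NA` for waves a country did not participate in. Row and column names are
#'   optional if `countries`/`waves` are given.
#' @param countries character vector of unique country/region codes
#'   (e.g. `"BE-VLG"`). Defaults to `rownames(values)`.
#' @param waves character vector of wave labels (e.g. `"2013/14"`), strictly
#'   increasing in calendar time. Defaults to `colnames(values)`.
#' @param gender `"boys"` or `"girls"` (or any label identifying the stratum).
#' @param range_check verify that all non-missing cells lie in [0, 100]
#'   (default `TRUE`; synthetic panels with unclipped Gaussian noise may
#'   disable it).
#' @return An object of class `prevalence_panel`: a list with elements
#'   `gender`, `countries`, `waves`, `values` (the named matrix) and `m`
#'   (per-country count of non-missing waves).
#' @seealso [load_prevalence_table()], [wave_change()], [generate_panel()]
#' @export
prevalence_panel <- function(values, countries = rownames(values),
                             waves = colnames(values), gender = "boys",
                             range_check = TRUE) {
  values <- as.matrix(values)
  if (is.null(countries) || is.null(waves))
    stop("'values' needs row/column names, or 'countries' and 'waves' must be given")
  if (length(countries) != nrow(values) || length(waves) != ncol(values))
    stop("dimensions of 'values' do not match 'countries' x 'waves'")
  countries <- as.character(countries)
  waves <- as.character(waves)
  if (anyDuplicated(countries))
    stop("duplicate country code: ", countries[duplicated(countries)][1L])
  yrs <- vapply(waves, wave_year, numeric(1))
  if (any(diff(yrs) <= 0))
    stop("wave labels must be strictly increasing in calendar time")
  bad <- if (range_check)
    which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  else matrix(integer(0), 0L, 2L)
  if (nrow(bad) > 0L)
    stop(sprintf("prevalence outside [0, 100] at row '%s', column '%s'",
                 countries[bad[1L, 1L]], waves[bad[1L, 2L]]))
  m <- rowSums(!is.na(values))
  if (any(m < 1L))
    stop("country with no observed waves: ", countries[which(m < 1L)[1L]])
  dimnames(values) <- list(countries, waves)
  structure(list(gender = gender, countries = countries, waves = waves,
                 values = values, m = m),
            class = "prevalence_panel")
}

#' @export
print.prevalence_panel <- function(x, ...) {
  cat(sprintf("Prevalence panel (%s): %d countries x %d waves, %d observed cells\n",
              x$gender, length(x$countries), length(x$waves), sum(x$m)))
  cat("waves:", paste(x$waves, collapse = " "), "\n")
  invisible(x)
}

#' Read a prevalence table from CSV
#'
#' The expected layout mirrors the published HBSC prevalence tables: a
#' `country` column followed by one column per survey wave, blank cells
#' marking waves a country did not participate in.
#'
#' @param path path to a CSV file (UTF-8, header `country,<wave>,<wave>,...`).
#' @param gender stratum label stored on the panel, `"boys"` or `"girls"`.
#' @return A [prevalence_panel()].
#' @examples
#' boys <- load_prevalence_table(
#'   system.file("extdata", "hbsc_boys.csv", package = "dpgrowth"), "boys")
#' boys$values["FI", "1985/86"]
#' @export
load_prevalence_table <- function(path, gender = c("boys", "girls")) {
  gender <- match.arg(gender)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L || names(raw)[1L] != "country")
    stop("malformed header in ", path, ": first column must be 'country'")
  waves <- names(raw)[-1L]
  if (!all(grepl("^[0-9]{4}/[0-9]{2}$", waves)))
    stop("malformed header: wave columns must look like '2013/14' (got: ",
         paste(waves[!grepl("^[0-9]{4}/[0-9]{2}$", waves)], collapse = ", "), ")")
  countries <- raw$country
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1L, , drop = FALSE]], countries[bad[1L, 1L]],
                 waves[bad[1L, 2L]]))
  dimnames(num) <- list(countries, waves)
  prevalence_panel(num, gender = gender)
}

#' Write a prevalence panel to CSV
#'
#' Inverse of [load_prevalence_table()]: missing cells are written as empty
#' strings, so a write/read round trip reproduces the panel exactly.
#'
#' @param panel a [prevalence_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prevalence_table <- function(panel, path) {
  stopifnot(inherits(panel, "prevalence_panel"))
  df <- data.frame(country = panel$countries,
                   as.data.frame(panel$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Map wave labels to survey years and scaled time
#'
#' A wave label such as `"2013/14"` denotes fieldwork spanning a school year;
#' the later calendar year (2014) is used as the survey year, matching how
#' results for these waves are usually cited (2018 for 2013/14's successor,
#' 2022 for the forecast wave). Scaled time is
#' `u = (survey_year - center_year) / scale_years`, which keeps the
#' polynomial basis well conditioned over the 1986--2022 span: with the
#' defaults, u runs from -1 (1985/86) to 1.25 (2021/22).
#'
#' @param center_year year mapped to u = 0 (default 2002).
#' @param scale_years scaling denominator in years (default 16).
#' @return An object of class `time_mapping`.
#' @export
time_mapping <- function(center_year = 2002, scale_years = 16) {
  stopifnot(is.numeric(center_year), is.numeric(scale_years), scale_years > 0)
  structure(list(center_year = center_year, scale_years = scale_years),
            class = "time_mapping")
}

wave_year <- function(wave_label) {
  if (!grepl("^[0-9]{4}/[0-9]{2}$", wave_label))
    stop("unknown wave label: '", wave_label, "'")
  as.numeric(substr(wave_label, 1L, 4L)) + 1
}

#' Scaled time for a wave label
#'
#' @param mapping a [time_mapping()].
#' @param wave_label wave label, e.g. `"2001/02"`; the forecast label
#'   `"2021/22"` is valid even though no panel observes it.
#' @return scaled time u (numeric scalar, vectorised over `wave_label`).
#' @examples
#' scaled_time(time_mapping(), "2001/02")  # 0
#' scaled_time(time_mapping(), "2021/22")  # 1.25
#' @export
scaled_time <- function(mapping, wave_label) {
  stopifnot(inherits(mapping, "time_mapping"))
  (vapply(wave_label, wave_year, numeric(1), USE.NAMES = FALSE) -
     mapping$center_year) / mapping$scale_years
}

#' Wave-to-wave change in prevalence
#'
#' Difference in percentage points between two observed waves of one country,
#' rounded to one decimal with halves away from zero (so 7.17 prints as 7.2),
#' the convention used when such changes are reported.
#'
#' @param panel a [prevalence_panel()].
#' @param country country code present in the panel.
#' @param wave_a,wave_b wave labels; the change is `value_b - value_a`.
#' @return numeric scalar, percentage points at one decimal.
#' @export
wave_change <- function(panel, country, wave_a, wave_b) {
  stopifnot(inherits(panel, "prevalence_panel"))
  if (!country %in% panel$countries) stop("unknown country: ", country)
  for (w in c(wave_a, wave_b))
    if (!w %in% panel$waves) stop("unknown wave: ", w)
  va <- panel$values[country, wave_a]
  vb <- panel$values[country, wave_b]
  if (is.na(va)) stop(country, " has no observation in wave ", wave_a)
  if (is.na(vb)) stop(country, " has no observation in wave ", wave_b)
  round_half_away(vb - va, 1L)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
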