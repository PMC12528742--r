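#' Construct a development dataset
#'
#' A development dataset holds one row per reared individual: the development
#' time \code{dev_time} in days (time from a defined start, e.g. oviposition or
#' hatch, to a landmark stage), the constant rearing temperature \code{temp} in
#' degrees Celsius, and optional covariates \code{sex} (\code{"M"}, \code{"F"}
#' or \code{NA} for unknown), body \code{length} in mm and \code{weight} in mg.
#' Individuals that died before completing development do not appear as rows;
#' there is no censoring model.
#'
#' @param dev_time numeric vector of development times in days; must be > 0.
#' @param temp numeric vector of rearing temperatures in degrees Celsius.
#' @param sex optional character vector with values \code{"M"}, \code{"F"} or
#'   \code{NA}.
#' @param length optional numeric vector of body lengths in mm (> 0 or
#'   \code{NA}).
#' @param weight optional numeric vector of body weights in mg (> 0 or
#'   \code{NA}).
#' @param species_label free-text label for the dataset.
#' @return An object of class \code{"development_data"}: a data frame with
#'   columns \code{dev_time}, \code{temp}, \code{sex}, \code{length},
#'   \code{weight} and a \code{species_label} attribute.
#' @examples
#' d <- development_data(dev_time = c(109.79, 141.13, 66.25),
#'                       temp = c(15, 15, 15))
#' nrow(d)
#' @export
development_data <- function(dev_time, temp, sex = NULL, length = NULL,
                             weight = NULL, species_label = "") {
  n <- base::length(dev_time)
  if (n == 0L) stop("empty dataset: at least one record is required")
  dev_time <- as.numeric(dev_time)
  temp <- as.numeric(temp)
  if (base::length(temp) != n) stop("dev_time and temp must have equal length")
  if (anyNA(dev_time) || anyNA(temp))
    stop("dev_time and temp must not contain missing values")
  if (any(dev_time <= 0)) stop("dev_time must be strictly positive")
  if (any(!is.finite(temp))) stop("temp must be finite")
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  sex <- as.character(fill(sex, NA_character_))
  bad_sex <- !is.na(sex) & !sex %in% c("M", "F")
  if (any(bad_sex)) stop("sex must be 'M', 'F' or NA")
  length <- as.numeric(fill(length, NA_real_))
  weight <- as.numeric(fill(weight, NA_real_))
  if (any(!is.na(length) & length <= 0)) stop("length must be > 0 when present")
  if (any(!is.na(weight) & weight <= 0)) stop("weight must be > 0 when present")
  if (base::length(sex) != n || base::length(length) != n ||
      base::length(weight) != n)
    stop("covariate vectors must match the number of records")
  out <- data.frame(dev_time = dev_time, temp = temp, sex = sex,
                    length = length, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "species_label") <- as.character(species_label)
  class(out) <- c("development_data", "data.frame")
  out
}

#' @export
print.development_data <- function(x, ...) {
  cat(sprintf("Development dataset: %d records, %d temperature(s)%s\n",
              nrow(x), base::length(unique(x$temp)),
              if (nzchar(attr(x, "species_label")))
                paste0(" [", attr(x, "species_label"), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# canonical CSV column names; column_map may supply aliases
.canonical_cols <- c(dev_time = "dev_time_days", temp = "temp_C", sex = "sex",
                     length = "length_mm", weight = "weight_mg")

.assert_dataset <- function(data, min_temps = 1L) {
  if (!inherits(data, "development_data"))
    stop("expected a development_data object; see development_data()")
  if (nrow(data) == 0L) stop("empty dataset")
  if (base::length(unique(data$temp)) < min_temps)
    stop(sprintf("at least %d distinct temperatures are required", min_temps))
  invisible(data)
}

#' Read a rearing dataset from CSV
#'
#' Reads a comma-separated, '.'-decimal, UTF-8 CSV with a header row. The
#' canonical columns are \code{dev_time_days}, \code{temp_C}, \code{sex},
#' \code{length_mm}, \code{weight_mg}; \code{column_map} maps canonical names
#' to the names actually present in the file. Rows with missing development
#' time or temperature are dropped with a warning that reports the count.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   (e.g. \code{"dev_time_days"}) to file column names.
#' @param species_label label stored on the returned dataset.
#' @return A \code{\link{development_data}} object; the number of dropped rows
#'   is available as \code{attr(x, "n_dropped")}.
#' @examples
#' # six example development records of Creophilus maxillosus
#' csv <- system.file("extdata", "creophilus_example.csv",
#'                    package = "thermomix")
#' read_development_csv(csv, species_label = "C. maxillosus")
#' @export
read_development_csv <- function(path, column_map = NULL, species_label = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("empty input: %s has no data rows", path))
  resolve <- function(canon) {
    nm <- if (!is.null(column_map) && canon %in% names(column_map))
      column_map[[canon]] else canon
    if (nm %in% names(raw)) nm else NA_character_
  }
  for (req in c("dev_time_days", "temp_C")) {
    if (is.na(resolve(req)))
      stop(sprintf("missing required column '%s' in %s", req, path))
  }
  num_col <- function(canon, what) {
    nm <- resolve(canon)
    if (is.na(nm)) return(rep(NA_real_, nrow(raw)))
    txt <- raw[[nm]]
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(trimws(txt)) & is.na(out))
    if (canon %in% c("dev_time_days", "temp_C") && base::length(bad) > 0L)
      stop(sprintf("non-numeric %s value '%s' at data row %d", what,
                   txt[bad[1L]], bad[1L]))
    out[!nzchar(trimws(ifelse(is.na(txt), "", txt)))] <- NA_real_
    out
  }
  dev_time <- num_col("dev_time_days", "dev_time_days")
  temp <- num_col("temp_C", "temp_C")
  keep <- !is.na(dev_time) & !is.na(temp)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(sprintf("dropped %d row(s) with missing dev_time or temp",
                    n_dropped))
  if (!any(keep)) stop("no usable rows after dropping missing dev_time/temp")
  sex_nm <- resolve("sex")
  sex <- if (is.na(sex_nm)) NULL else {
    s <- trimws(raw[[sex_nm]])
    s[!s %in% c("M", "F")] <- NA_character_
    s[keep]
  }
  out <- development_data(
    dev_time = dev_time[keep], temp = temp[keep], sex = sex,
    length = num_col("length_mm", "length_mm")[keep],
    weight = num_col("weight_mg", "weight_mg")[keep],
    species_label = species_label)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a rearing dataset to CSV
#'
#' Writes the canonical CSV schema understood by
#' \code{\link{read_development_csv}}.
#'
#' @param data a \code{\link{development_data}} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_development_csv <- function(data, path) {
  .assert_dataset(data)
  out <- data.frame(dev_time_days = format(data$dev_time, digits = 15L,
                                           trim = TRUE, scientific = FALSE),
                    temp_C = format(data$temp, digits = 15L, trim = TRUE,
                                    scientific = FALSE),
                    sex = ifelse(is.na(data$sex), "", data$sex),
                    length_mm = ifelse(is.na(data$length), "",
                                       format(data$length, digits = 15L,
                                              trim = TRUE, scientific = FALSE)),
                    weight_mg = ifelse(is.na(data$weight), "",
                                       format(data$weight, digits = 15L,
                                              trim = TRUE, scientific = FALSE)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted mixture model to JSON
#'
#' Serializes a \code{\link{weibull_mixture}} to a JSON document with a
#' \code{components} array (\code{weight}, \code{shape}, \code{scale},
#' \code{t0} per component) and a \code{meta} object (\code{loglik},
#' \code{n_obs}, \code{n_iter}, \code{converged}, \code{seed}). Numbers are
#' written at full double precision.
#'
#' @param model a \code{\link{weibull_mixture}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_model_json <- function(model, path) {
  .assert_mixture(model)
  comps <- lapply(seq_len(nrow(model$components)), function(i) {
    r <- model$components[i, ]
    list(weight = r$weight, shape = r$shape, scale = r$scale, t0 = r$t0)
  })
  doc <- list(components = comps,
              meta = list(loglik = model$loglik, n_obs = model$n_obs,
                          n_iter = model$n_iter, converged = model$converged,
                          seed = model$seed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted mixture model from JSON
#'
#' Reads the schema written by \code{\link{write_model_json}} and re-validates
#' all model invariants.
#'
#' @param path path to the JSON file.
#' @return A \code{\link{weibull_mixture}}.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed JSON in %s: %s", path,
                                 conditionMessage(e))))
  if (is.null(doc$components) || base::length(doc$components) == 0L)
    stop("model JSON must contain a non-empty 'components' array")
  get_num <- function(x, nm) {
    v <- x[[nm]]
    if (is.null(v) || !is.numeric(v))
      stop(sprintf("component field '%s' missing or non-numeric", nm))
    as.numeric(v)
  }
  comps <- do.call(rbind, lapply(doc$components, function(cc) {
    data.frame(weight = get_num(cc, "weight"), shape = get_num(cc, "shape"),
               scale = get_num(cc, "scale"), t0 = get_num(cc, "t0"))
  }))
  meta <- doc$meta
  weibull_mixture(
    weight = comps$weight, shape = comps$shape, scale = comps$scale,
    t0 = comps$t0,
    loglik = if (is.null(meta$loglik)) NA_real_ else as.numeric(meta$loglik),
    n_obs = if (is.null(meta$n_obs)) 0L else as.integer(meta$n_obs),
    n_iter = if (is.null(meta$n_iter)) 0L else as.integer(meta$n_iter),
    converged = isTRUE(meta$converged),
    seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed),
    sort_components = FALSE)
}
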