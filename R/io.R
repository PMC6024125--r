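#' Read a dataset from disk
#'
#' Two dialects are supported.  `"csv-bundle"` is the package's native
#' format: a directory holding `individuals.csv`, `detections.csv` (wide,
#' one column per occasion), `fecundity.csv`, `unbanded.csv` and
#' `occasions.csv`.  `"bugs-dump"` is the classic S-PLUS/R dump dialect used
#' by BUGS supplements, restricted to the
#' `list(name = value, name = c(...), name = structure(.Data = c(...), .Dim = c(...)))`
#' subset; the `variables` mapping names the dump entries holding each model
#' input.
#'
#' @param path directory (csv-bundle) or file (bugs-dump).
#' @param format `"csv-bundle"` or `"bugs-dump"`.
#' @param variables for bugs-dump: named list mapping model inputs to dump
#'   variable names.  Recognized entries: `detections`, `first_occasion`,
#'   `sex`, `origin`, `banding_method`, `fledglings`, `female`, `fec_year`,
#'   `density`, `unbanded`, `first_interval_fraction`.
#' @return a list with elements `capture_history` ([capture_history()]),
#'   `fecundity` ([fecundity_records()]) and `unbanded`
#'   ([unbanded_counts()]), cross-validated.
#' @export
read_dataset <- function(path, format = c("csv-bundle", "bugs-dump"),
                         variables = list()) {
  format <- match.arg(format)
  data <- switch(format,
                 "csv-bundle" = read_csv_bundle(path),
                 "bugs-dump" = read_bugs_dataset(path, variables))
  validate_dataset(data)
}

read_csv_bundle <- function(path) {
  need <- c("individuals.csv", "detections.csv", "fecundity.csv",
            "unbanded.csv", "occasions.csv")
  files <- file.path(path, need)
  missing <- need[!file.exists(files)]
  if (length(missing))
    stop("csv-bundle at ", path, " is missing: ",
         paste(missing, collapse = ", "))
  ind <- read.csv(files[1], stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
  det <- read.csv(files[2], stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
  fec <- read.csv(files[3], stringsAsFactors = FALSE,
                  colClasses = c(female_id = "character"))
  unb <- read.csv(files[4], stringsAsFactors = FALSE)
  occ <- read.csv(files[5], stringsAsFactors = FALSE)
  ind$sex[ind$sex == "U"] <- "unknown"
  det <- det[match(ind$id, det$id), , drop = FALSE]
  mat <- as.matrix(det[, setdiff(names(det), "id"), drop = FALSE])
  fif <- if ("frac_to_next" %in% names(occ) && nrow(occ) > 1)
    occ$frac_to_next[1] else 1
  ch <- capture_history(
    mat,
    individuals(ind$id, ind$sex, ind$origin, ind$banding_method,
                ind$first_occasion),
    occasions = data.frame(occasion = occ$occasion,
                           label = as.character(occ$label),
                           stringsAsFactors = FALSE),
    first_interval_fraction = fif)
  list(capture_history = ch,
       fecundity = fecundity_records(fec$female_id, fec$year, fec$fledglings,
                                     fec$density),
       unbanded = unbanded_counts(unb$occasion, unb$sex, unb$count))
}

#' Write a dataset as a csv-bundle
#'
#' Inverse of [read_dataset()] for the csv-bundle format:
#' `read_dataset(write_dataset(x, d), "csv-bundle")` reproduces `x` exactly.
#'
#' @param data list with `capture_history`, `fecundity`, `unbanded`.
#' @param path directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ch <- data$capture_history
  write.csv(ch$individuals, file.path(path, "individuals.csv"),
            row.names = FALSE, quote = TRUE)
  det <- data.frame(id = ch$individuals$id, ch$detections, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(det) <- c("id", paste0("occ_", seq_len(ncol(ch$detections)) - 1L))
  write.csv(det, file.path(path, "detections.csv"), row.names = FALSE)
  write.csv(as.data.frame(data$fecundity), file.path(path, "fecundity.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(data$unbanded), file.path(path, "unbanded.csv"),
            row.names = FALSE)
  occ <- ch$occasions
  occ$frac_to_next <- c(ch$first_interval_fraction,
                        rep(1, nrow(occ) - 1))[seq_len(nrow(occ))]
  occ$frac_to_next[nrow(occ)] <- NA
  write.csv(occ, file.path(path, "occasions.csv"), row.names = FALSE)
  invisible(path)
}

#' Parse a BUGS-format data dump
#'
#' Handles the `list(...)` dump dialect used by classic BUGS: scalar values,
#' `c(...)` vectors and `structure(.Data = c(...), .Dim = c(...))` arrays
#' (column-filled by `.Dim`, as R's `structure` does).  Anything outside this
#' subset is rejected.  Parse errors report the offending line.
#'
#' @param path text file containing one or more `name <- value` assignments
#'   or a single `list(...)` expression.
#' @return a named list of numeric vectors/matrices.
#' @export
read_bugs_dump <- function(path) {
  txt <- readLines(path, warn = FALSE)
  exprs <- tryCatch(parse(text = txt, keep.source = TRUE),
                    error = function(e) {
                      ln <- sub(".*line ([0-9]+).*", "\\1",
                                conditionMessage(e))
                      stop("malformed BUGS dump in ", path,
                           if (grepl("^[0-9]+$", ln))
                             paste0(" at line ", ln),
                           ": ", conditionMessage(e), call. = FALSE)
                    })
  check_bugs_expr <- function(e) {
    if (is.atomic(e) || is.name(e)) return(invisible())
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (fn %in% c("<-", "=")) {
        check_bugs_expr(e[[3]])
        return(invisible())
      }
      if (!fn %in% c("list", "c", "structure", "-", "+"))
        stop("unsupported construct in BUGS dump: ", fn, call. = FALSE)
      for (a in as.list(e)[-1]) check_bugs_expr(a)
      return(invisible())
    }
    stop("unsupported construct in BUGS dump", call. = FALSE)
  }
  env <- new.env(parent = baseenv())
  out <- list()
  for (e in exprs) {
    check_bugs_expr(e)
    v <- eval(e, env)
    if (is.list(v)) out[names(v)] <- v
  }
  vars <- ls(env)
  out[vars] <- mget(vars, envir = env)
  out
}

read_bugs_dataset <- function(path, variables) {
  v <- utils::modifyList(
    list(detections = "y", first_occasion = "f", sex = "sex",
         origin = "origin", banding_method = "band", fledglings = "fl",
         female = "fem", fec_year = "fyear", density = "dens",
         unbanded = "unb", first_interval_fraction = "fif"),
    variables)
  d <- read_bugs_dump(path)
  get_var <- function(nm, required = TRUE) {
    if (!v[[nm]] %in% names(d)) {
      if (required) stop("BUGS dump lacks variable '", v[[nm]],
                         "' (", nm, ")")
      return(NULL)
    }
    d[[v[[nm]]]]
  }
  det <- get_var("detections")
  if (is.null(dim(det))) stop("detections variable must have .Dim")
  n <- nrow(det)
  first <- get_var("first_occasion")
  sex_code <- get_var("sex", required = FALSE)
  origin_code <- get_var("origin", required = FALSE)
  band_code <- get_var("banding_method", required = FALSE)
  sex <- if (is.null(sex_code)) rep("unknown", n) else
    c("male", "female", "unknown")[sex_code]
  origin <- if (is.null(origin_code)) rep("wild-born", n) else
    c("translocated", "wild-born")[origin_code]
  band <- if (is.null(band_code)) rep("nestling", n) else
    c("nestling", "fledgling")[band_code]
  band[origin == "translocated"] <- "not-applicable"
  fif <- get_var("first_interval_fraction", required = FALSE)
  ch <- capture_history(det,
                        individuals(sprintf("b%03d", seq_len(n)), sex, origin,
                                    band, first),
                        first_interval_fraction = if (is.null(fif)) 1 else fif)
  fl <- get_var("fledglings", required = FALSE)
  fec <- if (is.null(fl)) fecundity_records() else
    fecundity_records(sprintf("b%03d", get_var("female")),
                      get_var("fec_year"), fl, get_var("density"))
  unb <- get_var("unbanded", required = FALSE)
  ub <- if (is.null(unb)) unbanded_counts() else
    unbanded_counts(unb[, 1], c("male", "female", "unknown")[unb[, 2]],
                    unb[, 3])
  list(capture_history = ch, fecundity = fec, unbanded = ub)
}
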