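#' Load a steroid analyte/ratio registry
#'
#' Reads a sectioned, tab-separated registry file with an `[analytes]`
#' table (abbreviation, full name, molar unit, conjugation flag,
#' optional unconjugated parent, steroid class, reference control
#' median/quartiles) and a `[ratios]` table (ratio name, `;`-joined
#' numerator and denominator analyte keys, enzyme panel, display
#' scale). All referential integrity invariants are checked on load.
#'
#' @param path Path to a registry file. Defaults to the packaged
#'   81-analyte catalog.
#' @return A `steroid_catalog` object: a list with tibbles `analytes`
#'   and `ratios`.
#' @examples
#' cat81 <- load_catalog()
#' nrow(cat81$analytes)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "steroid_catalog.txt",
                        package = "steroidome", mustWork = TRUE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  ia <- which(lines == "[analytes]")
  ir <- which(lines == "[ratios]")
  if (length(ia) != 1 || length(ir) != 1 || ir <= ia) {
    stop("registry file must contain one [analytes] and one [ratios] section")
  }
  read_section <- function(x) {
    x <- x[nzchar(x)]
    readr::read_tsv(I(paste(x, collapse = "\n")),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  analytes <- read_section(lines[(ia + 1):(ir - 1)])
  ratios <- read_section(lines[(ir + 1):length(lines)])
  analytes <- dplyr::mutate(
    analytes,
    conjugated = .data$conjugated == "TRUE",
    dplyr::across(dplyr::any_of(c("ctrl_median", "ctrl_q1", "ctrl_q3")),
                  as.numeric)
  )
  if (!"note" %in% names(analytes)) analytes$note <- NA_character_
  ratios <- dplyr::mutate(ratios,
                          display_scale = as.integer(.data$display_scale))
  if (!"note" %in% names(ratios)) ratios$note <- NA_character_
  catalog <- structure(list(analytes = analytes, ratios = ratios),
                       class = "steroid_catalog")
  validate_catalog(catalog)
  catalog
}

#' Validate a steroid catalog
#'
#' Checks key uniqueness, allowed molar units, parent references
#' (conjugated analytes must either point at a registered unconjugated
#' parent or carry a note explaining the absence), and ratio
#' referential integrity (all keys registered, numerator and
#' denominator non-empty and disjoint).
#'
#' @param catalog A `steroid_catalog`.
#' @return The catalog, invisibly; errors name the offending entry.
#' @export
validate_catalog <- function(catalog) {
  an <- catalog$analytes
  dup <- an$abbreviation[duplicated(an$abbreviation)]
  if (length(dup)) stop("duplicate analyte key: ", paste(dup, collapse = ", "))
  bad_unit <- an$abbreviation[!an$unit %in% c("pM", "nM", "µM")]
  if (length(bad_unit)) {
    stop("unknown unit for analyte: ", paste(bad_unit, collapse = ", "))
  }
  free_keys <- an$abbreviation[!an$conjugated]
  conj <- dplyr::filter(an, .data$conjugated)
  bad_parent <- conj$abbreviation[
    !is.na(conj$parent) & !conj$parent %in% free_keys]
  if (length(bad_parent)) {
    stop("dangling parent reference: ", paste(bad_parent, collapse = ", "))
  }
  orphan <- conj$abbreviation[is.na(conj$parent) & is.na(conj$note)]
  if (length(orphan)) {
    stop("conjugated analyte without parent or explanatory note: ",
         paste(orphan, collapse = ", "))
  }
  ra <- catalog$ratios
  for (i in seq_len(nrow(ra))) {
    num <- ratio_keys(ra$numerator[i])
    den <- ratio_keys(ra$denominator[i])
    if (!length(num) || !length(den)) {
      stop("empty ratio side in: ", ra$name[i])
    }
    unknown <- setdiff(c(num, den), an$abbreviation)
    if (length(unknown)) {
      stop("ratio '", ra$name[i], "' references unknown analyte: ",
           paste(unknown, collapse = ", "))
    }
    if (length(intersect(num, den))) {
      stop("ratio '", ra$name[i], "' has overlapping numerator/denominator")
    }
  }
  invisible(catalog)
}

ratio_keys <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' @export
print.steroid_catalog <- function(x, ...) {
  an <- x$analytes
  cat(sprintf(
    "<steroid_catalog> %d analytes (%d unconjugated, %d conjugated), %d ratios in %d panels\n",
    nrow(an), sum(!an$conjugated), sum(an$conjugated),
    nrow(x$ratios), dplyr::n_distinct(x$ratios$panel)))
  invisible(x)
}

#' Write a catalog back to its registry format
#'
#' @param catalog A `steroid_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  an <- dplyr::mutate(catalog$analytes,
                      conjugated = ifelse(.data$conjugated, "TRUE", "FALSE"))
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    })
    c(paste(names(df), collapse = "\t"),
      do.call(paste, c(unname(df), sep = "\t")))
  }
  readr::write_lines(
    c("[analytes]", fmt(an), "[ratios]", fmt(catalog$ratios)), path)
  invisible(path)
}

#' Convert a molar concentration to nM
#'
#' The registry mixes pM, nM and µM scales; all ratio arithmetic is
#' done in nM.
#'
#' @param value Numeric concentrations (finite, non-negative).
#' @param unit One of `"pM"`, `"nM"`, `"µM"` (also accepts `"uM"`),
#'   recycled against `value`.
#' @return Concentrations in nM.
#' @examples
#' to_molar(260, "pM")  # 0.26 nM
#' to_molar(2.2, "µM")  # 2200 nM
#' @export
to_molar <- function(value, unit) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) stop("negative concentration")
  unit <- sub("^uM$", "µM", unit)
  fac <- c("pM" = 1e-3, "nM" = 1, "µM" = 1e3)[unit]
  if (anyNA(fac)) stop("unknown unit: ", paste(unique(unit[is.na(fac)]),
                                               collapse = ", "))
  unname(value * fac)
}

#' Evaluate enzyme-panel molar ratios on a concentration table
#'
#' Converts every analyte to nM using the units recorded on the table
#' (falling back to the catalog unit), then evaluates each registered
#' ratio per sample as the sum of its numerator analytes divided by the
#' sum of its denominator analytes. Missing constituents propagate to a
#' missing ratio; a zero denominator yields `NA` with a warning rather
#' than an error.
#'
#' @param data A concentration table: one row per subject, analyte
#'   columns named by catalog key, plus any metadata columns (carried
#'   through unchanged). Units are taken from `attr(data, "units")`, a
#'   named character vector, when present.
#' @param catalog A `steroid_catalog` (default: packaged catalog).
#' @param panel A panel name (e.g. `"SULT2A1_vs_STS"`), a vector of
#'   panel names, or `"all"`.
#' @param display If `TRUE`, multiply each ratio by its registered
#'   power-of-ten display scale; the default keeps ratios on the raw
#'   dimensionless scale.
#' @return A tibble with the table's metadata columns followed by one
#'   column per ratio name.
#' @examples
#' cat81 <- load_catalog()
#' tbl <- tibble::tibble(subject_id = "s1", E2 = 260, A = 3, T = 0.59)
#' attr(tbl, "units") <- c(E2 = "pM", A = "nM", T = "nM")
#' evaluate_ratios(tbl, cat81, panel = "CYP19A1")
#' @export
evaluate_ratios <- function(data, catalog = load_catalog(), panel = "all",
                            display = FALSE) {
  ra <- catalog$ratios
  if (!identical(panel, "all")) {
    unknown <- setdiff(panel, unique(ra$panel))
    if (length(unknown)) stop("unknown panel: ", paste(unknown, collapse = ", "))
    ra <- dplyr::filter(ra, .data$panel %in% !!panel)
  }
  present <- intersect(catalog$analytes$abbreviation, names(data))
  units <- attr(data, "units")
  unit_of <- stats::setNames(catalog$analytes$unit,
                             catalog$analytes$abbreviation)[present]
  if (!is.null(units)) {
    ov <- intersect(names(units), present)
    unit_of[ov] <- units[ov]
  }
  conc <- vapply(present, function(k) to_molar(data[[k]], unit_of[[k]]),
                 numeric(nrow(data)))
  conc <- matrix(conc, nrow = nrow(data),
                 dimnames = list(NULL, present))
  meta <- data[setdiff(names(data), catalog$analytes$abbreviation)]
  side_sum <- function(keys) {
    if (!all(keys %in% present)) return(rep(NA_real_, nrow(data)))
    rowSums(conc[, keys, drop = FALSE])
  }
  n_zero_den <- 0L
  vals <- lapply(seq_len(nrow(ra)), function(i) {
    num <- side_sum(ratio_keys(ra$numerator[i]))
    den <- side_sum(ratio_keys(ra$denominator[i]))
    zero <- !is.na(den) & den == 0
    if (any(zero)) {
      n_zero_den <<- n_zero_den + sum(zero)
      den[zero] <- NA_real_
    }
    r <- num / den
    if (display) r <- r * 10^ra$display_scale[i]
    r
  })
  if (n_zero_den > 0) {
    warning(n_zero_den, " ratio value(s) dropped due to zero denominator")
  }
  names(vals) <- ra$name
  out <- dplyr::bind_cols(tibble::as_tibble(meta), tibble::as_tibble(vals))
  attr(out, "panel_of") <- stats::setNames(ra$panel, ra$name)
  out
}
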