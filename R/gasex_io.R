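#' Canonical gas-exchange record schema
#'
#' The package reads and writes flat, long-format CSV with one row per
#' steady-state measurement and fixed headers: `record_id`, `line_id`,
#' `A` (net assimilation, umol m-2 s-1), `gsw` (stomatal conductance to
#' water vapour, mol m-2 s-1), `ci` and `ca` (intercellular / ambient CO2,
#' umol mol-1), `ppfd` (umol m-2 s-1), `phi_psii` (PSII operating
#' efficiency), `tleaf` (degC), `rh` (%), `spad` (optional chlorophyll
#' index) and `timestamp` (optional).  Decimal point ".", UTF-8, comma
#' separator.  A built-in alias map translates common instrument export
#' names (e.g. `Qin` -> `ppfd`, `PhiPS2` -> `phi_psii`, `CO2_s` -> `ca`,
#' `RHcham` -> `rh`); matching is case-insensitive.
#'
#' @return `gasex_columns()` returns the canonical column names;
#'   `default_alias_map()` the built-in alias map (canonical name ->
#'   character vector of aliases).
#' @name gasex_schema
NULL

#' @rdname gasex_schema
#' @export
gasex_columns <- function() {
  c("record_id", "line_id", "A", "gsw", "ci", "ca", "ppfd", "phi_psii",
    "tleaf", "rh", "spad", "timestamp")
}

.gasex_numeric_cols <- function() {
  c("A", "gsw", "ci", "ca", "ppfd", "phi_psii", "tleaf", "rh", "spad")
}

#' @rdname gasex_schema
#' @export
default_alias_map <- function() {
  list(
    record_id = c("obs", "observation", "id"),
    line_id   = c("genotype", "line", "accession"),
    A         = c("a", "photo", "anet", "assimilation"),
    gsw       = c("cond", "gs", "gsw_mol"),
    ci        = c("ci_umol", "intercellular_co2"),
    ca        = c("co2_s", "co2s", "co2_sample", "ca_umol"),
    ppfd      = c("qin", "q", "par", "parin", "qamb_in", "light"),
    phi_psii  = c("phips2", "phipsii", "phi_ps2", "phi2"),
    tleaf     = c("tleaf_c", "leaf_temp", "tleafcnd"),
    rh        = c("rhcham", "rh_s", "rel_humidity"),
    spad      = c("chlorophyll", "spad_value"),
    timestamp = c("time", "date_time", "hhmmss")
  )
}

#' Read an alias-map override from a YAML config file
#'
#' The file maps canonical column names to lists of aliases; entries are
#' merged over [default_alias_map()].
#'
#' @param path Path to a YAML file (`canonical: [alias1, alias2]`).
#' @return A named list usable as `column_map` in [read_gasex_records()].
#' @export
read_alias_map <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.list(user) || is.null(names(user))) {
    abort("alias config must be a named mapping: canonical -> aliases")
  }
  unknown <- setdiff(names(user), gasex_columns())
  if (length(unknown)) {
    abort(paste0("alias config names unknown canonical columns: ",
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(default_alias_map(), lapply(user, as.character))
}

## map raw header names to canonical names (case-insensitive); unknown
## headers are left untouched and carried through as opaque extras
.canonicalise_names <- function(nms, column_map) {
  lut <- character(0)
  for (canon in names(column_map)) {
    aliases <- unique(tolower(c(canon, column_map[[canon]])))
    lut[aliases] <- canon
  }
  hit <- lut[tolower(nms)]
  ifelse(is.na(hit), nms, hit)
}

#' Read gas-exchange records from CSV
#'
#' Reads a flat CSV of steady-state gas-exchange measurements into the
#' canonical schema (see [gasex_schema]).  Rows violating physical
#' invariants (`gsw > 0`, `ppfd >= 0`, `0 <= phi_psii <= 1`, `ca > 0`,
#' `ci >= 0`, `rh` in \[0, 100\]) or containing unparseable numeric cells
#' are returned flagged in the `qc_flag` column, never silently dropped,
#' so that `n_read = n_valid + n_flagged`.  Unknown columns are preserved
#' unchanged.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional alias map (canonical name -> aliases)
#'   overriding [default_alias_map()]; see [read_alias_map()].
#' @return A tibble with the canonical columns, any extra columns, and a
#'   `qc_flag` character column (`""` for clean rows, semicolon-joined
#'   codes otherwise).  Attributes `n_read`, `n_valid`, `n_flagged`
#'   report the counts.
#' @seealso [write_gasex_records()], [read_light_curves()]
#' @export
read_gasex_records <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  column_map <- column_map %||% default_alias_map()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- .canonicalise_names(names(raw), column_map)

  mandatory <- c("A", "gsw", "ci", "ppfd")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in setdiff(gasex_columns(), names(raw))) {
    raw[[col]] <- NA_character_
  }
  n <- nrow(raw)
  flags <- character(n)
  add_flag <- function(flags, idx, code) {
    flags[idx] <- ifelse(flags[idx] == "", code, paste(flags[idx], code, sep = ";"))
    flags
  }

  for (col in .gasex_numeric_cols()) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(parsed)
    if (any(bad)) flags <- add_flag(flags, bad, paste0("parse:", col))
    raw[[col]] <- parsed
  }
  if (all(is.na(raw$record_id))) raw$record_id <- paste0("r", seq_len(n))

  chk <- list(
    "invariant: gsw>0"        = !is.na(raw$gsw) & raw$gsw <= 0,
    "invariant: ppfd>=0"      = !is.na(raw$ppfd) & raw$ppfd < 0,
    "invariant: phi_psii in [0,1]" =
      !is.na(raw$phi_psii) & (raw$phi_psii < 0 | raw$phi_psii > 1),
    "invariant: ca>0"         = !is.na(raw$ca) & raw$ca <= 0,
    "invariant: ci>=0"        = !is.na(raw$ci) & raw$ci < 0,
    "invariant: rh in [0,100]" = !is.na(raw$rh) & (raw$rh < 0 | raw$rh > 100)
  )
  for (code in names(chk)) {
    if (any(chk[[code]])) flags <- add_flag(flags, chk[[code]], code)
  }

  out <- as_tibble(raw)
  out$qc_flag <- flags
  ord <- c(intersect(gasex_columns(), names(out)),
           setdiff(names(out), c(gasex_columns(), "qc_flag")), "qc_flag")
  out <- out[, ord]
  attr(out, "n_read") <- n
  attr(out, "n_flagged") <- sum(flags != "")
  attr(out, "n_valid") <- n - sum(flags != "")
  if (attr(out, "n_flagged") > 0) {
    message(attr(out, "n_flagged"), " of ", n, " record(s) flagged on read")
  }
  out
}

#' Write gas-exchange records to CSV
#'
#' Writes records in the canonical schema so that
#' `read_gasex_records(write_gasex_records(x))` reproduces `x`
#' field-for-field (numeric round-trip to full double precision; missing
#' values become empty cells and are preserved as missing).  The derived
#' `qc_flag` column is not written.
#'
#' @param records A tibble of records (canonical columns; extras kept).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gasex_records <- function(records, path) {
  records <- as_tibble(records)
  records$qc_flag <- NULL
  if (nrow(records) == 0 && ncol(records) == 0) {
    records <- tibble::as_tibble(
      setNames(rep(list(character(0)), length(gasex_columns())),
               gasex_columns()))
  }
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read light-response curves from long-format CSV
#'
#' Expects columns `curve_id`, `ppfd`, `A` (aliases accepted as for
#' records; `line_id` optional).  Within each curve, points are sorted by
#' increasing PPFD and duplicated PPFD values are averaged, so the result
#' is deterministic and order-independent.  Curves with fewer than 4
#' distinct points are flagged `"insufficient_points"` (unusable for
#' fitting) but still returned.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional alias map as in [read_gasex_records()].
#' @return A tibble with columns `curve_id`, `line_id`, `ppfd`, `A`,
#'   `curve_flag` (one value per curve, `""` if usable).
#' @export
read_light_curves <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  column_map <- column_map %||% default_alias_map()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- .canonicalise_names(names(raw), column_map)
  need <- c("curve_id", "ppfd", "A")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"line_id" %in% names(raw)) raw$line_id <- NA_character_
  raw$ppfd <- as.numeric(raw$ppfd)
  raw$A <- as.numeric(raw$A)

  out <- raw |>
    dplyr::group_by(curve_id, line_id, ppfd) |>
    dplyr::summarise(A = mean(A), .groups = "drop") |>
    dplyr::arrange(curve_id, ppfd) |>
    dplyr::group_by(curve_id) |>
    dplyr::mutate(curve_flag = ifelse(dplyr::n() < 4, "insufficient_points", "")) |>
    dplyr::ungroup()
  n_bad <- length(unique(out$curve_id[out$curve_flag != ""]))
  if (n_bad > 0) message(n_bad, " curve(s) flagged insufficient_points")
  out
}
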