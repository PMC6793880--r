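# Canonical column sets for the three tabular inputs. CSV (UTF-8, header
# row, "." decimal) is the sole exchange format; a column map lets arbitrary
# headers bind to these names.

.iso_cols <- c("fish_id", "species", "site", "area", "status",
               "length", "weight", "d13C", "d15N")
.diet_cols <- c("predator_id", "predator_species", "area",
                "prey_taxon", "prey_count", "prey_mass")
.survey_cols <- c("site", "transect_id", "depth_stratum", "benthic_habitat",
                  "kelp", "species", "count", "length")

.apply_column_map <- function(df, column_map, required, what) {
  if (!is.null(column_map)) {
    bad <- setdiff(unname(unlist(column_map)), names(df))
    if (length(bad))
      stop(sprintf("%s: mapped columns absent from file: %s",
                   what, paste(bad, collapse = ", ")))
    for (canon in names(column_map)) {
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: required columns missing: %s",
                 what, paste(missing, collapse = ", ")))
  df
}

.check_numeric_rows <- function(df, cols, id_col, what, allow_na = character()) {
  for (cc in cols) {
    x <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(x) & !(cc %in% allow_na & is.na(df[[cc]])))
    if (length(bad)) {
      ids <- if (id_col %in% names(df)) df[[id_col]][bad] else bad
      stop(sprintf("%s: non-numeric or missing '%s' in row(s) %s (%s: %s)",
                   what, cc, paste(bad, collapse = ", "), id_col,
                   paste(utils::head(ids, 5), collapse = ", ")))
    }
    df[[cc]] <- x
  }
  df
}

#' Read per-fish isotope records from CSV
#'
#' Reads and validates the per-fish table: grouping labels (species, site,
#' area, protection status), total length (cm), wet weight (g, may be
#' missing) and the two isotope signatures `d13C` and `d15N` (permil).
#' `status` is coerced to an ordered factor `fished < protected`. Rows with
#' non-finite isotope values or non-positive lengths are rejected with
#' row-indexed diagnostics; missing weight is allowed (isotope analysis never
#' uses it).
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional named list mapping canonical names (e.g.
#'   `d13C`) to the file's headers, e.g. `list(d13C = "delta13C")`.
#' @return A `data.frame` of validated isotope records.
#' @seealso [validate_hierarchy()], [write_isotope_csv()]
#' @export
read_isotope_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_isotope_records(df, column_map)
}

#' Coerce a data frame to validated isotope records
#'
#' @param df A data frame holding the columns described in
#'   [read_isotope_csv()] (possibly under other names).
#' @inheritParams read_isotope_csv
#' @return A validated isotope-record `data.frame`.
#' @export
as_isotope_records <- function(df, column_map = NULL) {
  df <- .apply_column_map(df, column_map, .iso_cols, "isotope records")
  df <- .check_numeric_rows(df, c("d13C", "d15N", "length"),
                            "fish_id", "isotope records")
  df$weight <- suppressWarnings(as.numeric(df$weight))
  if (any(df$length <= 0))
    stop("isotope records: non-positive length in row(s) ",
         paste(which(df$length <= 0), collapse = ", "))
  if (any(!is.na(df$weight) & df$weight <= 0))
    stop("isotope records: non-positive weight")
  if (any(df$d13C <= -1000) || any(df$d15N <= -1000))
    stop("isotope records: delta values must exceed -1000 permil")
  st <- as.character(df$status)
  ok <- st %in% c("fished", "protected")
  if (!all(ok))
    stop("isotope records: status must be 'fished' or 'protected'; offending row(s) ",
         paste(which(!ok), collapse = ", "))
  df$status <- factor(st, levels = c("fished", "protected"), ordered = TRUE)
  for (cc in c("fish_id", "species", "site", "area"))
    df[[cc]] <- as.character(df[[cc]])
  df[, .iso_cols]
}

#' Write isotope records to CSV
#'
#' Round-trip companion to [read_isotope_csv()]: `read(write(x))` reproduces
#' the field values exactly (numeric columns are written with full precision).
#'
#' @param records Isotope record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(records, path) {
  out <- records
  out$status <- as.character(out$status)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read stomach-content (diet) records from CSV
#'
#' One row per predator-by-prey-taxon observation: prey count (integer,
#' at least 1) and total prey wet mass (g, non-negative). Duplicate
#' (predator, taxon) rows are aggregated by summation.
#'
#' @inheritParams read_isotope_csv
#' @return A `data.frame` of diet records, aggregated per predator and taxon.
#' @export
read_diet_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .apply_column_map(df, column_map, .diet_cols, "diet records")
  df <- .check_numeric_rows(df, c("prey_count", "prey_mass"),
                            "predator_id", "diet records")
  if (any(df$prey_count < 1)) stop("diet records: prey_count must be >= 1")
  if (any(df$prey_mass < 0)) stop("diet records: prey_mass must be >= 0")
  agg <- stats::aggregate(df[c("prey_count", "prey_mass")],
                          df[c("predator_id", "predator_species",
                               "area", "prey_taxon")], sum)
  agg[order(agg$predator_id, agg$prey_taxon), , drop = FALSE]
}

#' Read belt-transect survey records from CSV
#'
#' One row per species observation on a transect: depth stratum
#' (`shallow` < `deep`), ordinal benthic habitat class 1..6 (gravel to
#' bedrock), ordinal kelp canopy class 0..2 (zero/fragmented/full), fish
#' count and estimated length (cm).
#'
#' @inheritParams read_isotope_csv
#' @return A `data.frame` of validated survey records.
#' @export
read_survey_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .apply_column_map(df, column_map, .survey_cols, "survey records")
  df <- .check_numeric_rows(df, c("benthic_habitat", "kelp", "count", "length"),
                            "transect_id", "survey records")
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("survey records: count must be a non-negative integer")
  if (!all(df$benthic_habitat %in% 1:6))
    stop("survey records: benthic_habitat must be an ordinal code 1..6")
  if (!all(df$kelp %in% 0:2))
    stop("survey records: kelp must be an ordinal code 0..2")
  if (!all(df$depth_stratum %in% c("shallow", "deep")))
    stop("survey records: depth_stratum must be 'shallow' or 'deep'")
  df$depth_stratum <- factor(df$depth_stratum,
                             levels = c("shallow", "deep"), ordered = TRUE)
  df
}

#' Summarize the sampling hierarchy and flag non-estimable groups
#'
#' Checks the nested design (sites within areas, one protection status per
#' area) and tabulates per species-by-area sample sizes. Groups with fewer
#' than `min_n` fish are flagged as non-estimable for ellipse fitting: the
#' covariance of two points is degenerate and the SEAc correction divides by
#' n - 2.
#'
#' @param records Isotope record data frame.
#' @param min_n Minimum group size for ellipse estimation (default 3).
#' @return A list with elements `areas` (area/status table), `sites`
#'   (site-to-area table), and `cells` (data frame of species, area, n,
#'   estimable flag).
#' @export
validate_hierarchy <- function(records, min_n = 3) {
  if (!nrow(records)) stop("no records")
  sa <- unique(records[c("site", "area")])
  dup <- sa$site[duplicated(sa$site)]
  if (length(dup))
    stop("structural error: site(s) assigned to more than one area: ",
         paste(unique(dup), collapse = ", "))
  as <- unique(records[c("area", "status")])
  dupa <- as$area[duplicated(as$area)]
  if (length(dupa))
    stop("structural error: area(s) with more than one status: ",
         paste(unique(dupa), collapse = ", "))
  tab <- as.data.frame(table(species = records$species, area = records$area),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$estimable <- tab$n >= min_n
  list(areas = as[order(as$area), ],
       sites = sa[order(sa$area, sa$site), ],
       cells = tab[order(tab$area, tab$species), ])
}
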