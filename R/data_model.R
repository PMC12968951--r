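#' @keywords internal
"_PACKAGE"

# Canonical CSV schemas ------------------------------------------------------

.TRAP_COLUMNS <- c("trap_id", "landscape_id", "tree_cover_250m",
                   "barrier_free_angle")
.LANDSCAPE_COLUMNS <- c("landscape_id", "tree_cover_2km")
.CAPTURE_COLUMNS <- c("trap_id", "species_id", "count", "origin", "guild")

.ORIGIN_LEVELS <- c("native", "non_native")
.GUILD_LEVELS <- c("longhorned", "bark", "ambrosia", "other")

.check_percent <- function(x, name, rows = seq_along(x)) {
  bad <- which(!is.finite(x) | x < 0 | x > 100)
  if (length(bad)) {
    stop(sprintf("column '%s' must lie in [0, 100]; violated at row(s) %s",
                 name, paste(rows[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a trap metadata table
#'
#' Reads the canonical `traps.csv` schema (columns `trap_id`, `landscape_id`,
#' `tree_cover_250m`, `barrier_free_angle`, optionally `urbanization_index`)
#' and validates it: percentages must lie in \[0, 100\] and trap ids must be
#' unique within each landscape. Both covariates are measured in a 250-m
#' buffer around the trap.
#'
#' @param path path to a CSV file (comma separated, header required, `.`
#'   decimal, UTF-8).
#' @return a `data.frame` of traps with one row per trap.
#' @seealso [read_capture_table()], [build_matrices()]
#' @export
read_trap_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trap_id = "character",
                                       landscape_id = "character"))
  validate_trap_table(df)
}

#' Validate an in-memory trap table
#'
#' @param df a data.frame with the `traps.csv` columns.
#' @return the validated data.frame, invisibly coerced to canonical types.
#' @export
validate_trap_table <- function(df) {
  .check_columns(df, .TRAP_COLUMNS, "trap table")
  df$trap_id <- as.character(df$trap_id)
  df$landscape_id <- as.character(df$landscape_id)
  df$tree_cover_250m <- as.numeric(df$tree_cover_250m)
  df$barrier_free_angle <- as.numeric(df$barrier_free_angle)
  .check_percent(df$tree_cover_250m, "tree_cover_250m")
  .check_percent(df$barrier_free_angle, "barrier_free_angle")
  if ("urbanization_index" %in% names(df) &&
      any(!is.na(df$urbanization_index))) {
    .check_percent(df$urbanization_index[!is.na(df$urbanization_index)],
                   "urbanization_index",
                   rows = which(!is.na(df$urbanization_index)))
  }
  dup <- duplicated(df[, c("landscape_id", "trap_id")])
  if (any(dup)) {
    stop(sprintf("duplicate trap_id within landscape at row(s): %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a landscape metadata table
#'
#' Reads `landscapes.csv` (`landscape_id`, `tree_cover_2km`); tree cover is
#' the percentage within a 2-km radius of the landscape centre.
#'
#' @param path path to a CSV file.
#' @return a data.frame with one row per landscape.
#' @export
read_landscape_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(landscape_id = "character"))
  .check_columns(df, .LANDSCAPE_COLUMNS, "landscape table")
  .check_percent(df$tree_cover_2km, "tree_cover_2km")
  if (anyDuplicated(df$landscape_id)) {
    stop("duplicate landscape_id in landscape table", call. = FALSE)
  }
  df
}

#' Read a capture-record table
#'
#' Reads `captures.csv` (`trap_id`, `species_id`, `count`, `origin`,
#' `guild`). Counts must be non-negative integers; `origin` must be one of
#' `native`/`non_native` and `guild` one of
#' `longhorned`/`bark`/`ambrosia`/`other`. Referential integrity against the
#' trap table is checked later, at matrix-construction time.
#'
#' @param path path to a CSV file.
#' @return a data.frame of capture records (possibly zero rows).
#' @export
read_capture_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trap_id = "character",
                                       species_id = "character"))
  validate_capture_table(df)
}

#' Validate an in-memory capture table
#' @param df a data.frame with the `captures.csv` columns.
#' @return the validated data.frame.
#' @export
validate_capture_table <- function(df) {
  .check_columns(df, .CAPTURE_COLUMNS, "capture table")
  if (nrow(df) == 0L) return(df)
  df$trap_id <- as.character(df$trap_id)
  df$species_id <- as.character(df$species_id)
  if (any(!nzchar(df$species_id))) {
    stop("species_id must be nonempty", call. = FALSE)
  }
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != floor(df$count))
  if (length(bad)) {
    stop(sprintf("count must be a nonnegative integer; violated at row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df$count <- as.integer(df$count)
  bad_origin <- setdiff(unique(df$origin), .ORIGIN_LEVELS)
  if (length(bad_origin)) {
    stop(sprintf("unknown origin token(s) %s; allowed: %s",
                 paste(sQuote(bad_origin), collapse = ", "),
                 paste(.ORIGIN_LEVELS, collapse = ", ")), call. = FALSE)
  }
  bad_guild <- setdiff(unique(df$guild), .GUILD_LEVELS)
  if (length(bad_guild)) {
    stop(sprintf("unknown guild token(s) %s; allowed: %s",
                 paste(sQuote(bad_guild), collapse = ", "),
                 paste(.GUILD_LEVELS, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write study tables to CSV
#'
#' Writers matching the reader schemas, so a written study round-trips to
#' identical objects.
#'
#' @param df the table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trap_table <- function(df, path) {
  utils::write.csv(validate_trap_table(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trap_table
#' @export
write_capture_table <- function(df, path) {
  utils::write.csv(validate_capture_table(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trap_table
#' @export
write_landscape_table <- function(df, path) {
  .check_columns(df, .LANDSCAPE_COLUMNS, "landscape table")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Matrix construction --------------------------------------------------------

#' Build species-by-trap matrices for one landscape
#'
#' Pools captures over the whole season into an abundance matrix (cells =
#' season-total counts per species and trap) and the derived binary incidence
#' matrix (1 = detected at least once). Species never detected in the
#' landscape are absent from the rows; traps with zero captures are retained
#' as all-zero columns, because a zero-catch trap is still a sampling unit.
#'
#' @param traps trap table (see [read_trap_table()]).
#' @param captures capture table (see [read_capture_table()]).
#' @param landscape_id the landscape to build matrices for.
#' @param origin optional filter: keep only records with this origin
#'   (`"native"` or `"non_native"`).
#' @param guild optional filter: keep only records of this guild.
#' @return a list with elements `abundance` and `incidence` (integer
#'   matrices, species rows in first-appearance order, trap columns in trap
#'   table order), and `landscape_id`.
#' @examples
#' traps <- data.frame(trap_id = c("t1", "t2"), landscape_id = "L1",
#'                     tree_cover_250m = c(60, 30), barrier_free_angle = c(80, 40))
#' caps <- data.frame(trap_id = c("t1", "t1", "t2"),
#'                    species_id = c("sp1", "sp1", "sp2"),
#'                    count = c(2, 3, 1), origin = "native", guild = "bark")
#' build_matrices(traps, caps, "L1")$abundance
#' @export
build_matrices <- function(traps, captures, landscape_id,
                           origin = NULL, guild = NULL) {
  traps <- validate_trap_table(traps)
  captures <- validate_capture_table(captures)
  trap_ids <- traps$trap_id[traps$landscape_id == landscape_id]
  if (length(trap_ids) < 1L) {
    stop(sprintf("landscape '%s' has no traps", landscape_id), call. = FALSE)
  }
  all_trap_ids <- traps$trap_id
  rec <- captures[captures$trap_id %in% trap_ids, , drop = FALSE]
  stray <- setdiff(unique(captures$trap_id), all_trap_ids)
  if (length(stray)) {
    stop(sprintf("capture records reference unknown trap_id(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(origin)) {
    origin <- match.arg(origin, .ORIGIN_LEVELS)
    rec <- rec[rec$origin == origin, , drop = FALSE]
  }
  if (!is.null(guild)) {
    guild <- match.arg(guild, .GUILD_LEVELS)
    rec <- rec[rec$guild == guild, , drop = FALSE]
  }
  species <- unique(rec$species_id)
  ab <- matrix(0L, nrow = length(species), ncol = length(trap_ids),
               dimnames = list(species, trap_ids))
  if (nrow(rec)) {
    agg <- stats::aggregate(count ~ species_id + trap_id, data = rec, FUN = sum)
    ab[cbind(agg$species_id, agg$trap_id)] <- as.integer(agg$count)
  }
  # drop species rows whose season total is zero (records with count 0 only)
  keep <- rowSums(ab) > 0L
  ab <- ab[keep, , drop = FALSE]
  inc <- (ab >= 1L) * 1L
  structure(list(abundance = ab, incidence = inc,
                 landscape_id = landscape_id),
            class = "trap_matrices")
}

#' @export
print.trap_matrices <- function(x, ...) {
  cat(sprintf("Species x trap matrices for landscape '%s': %d species, %d traps\n",
              x$landscape_id, nrow(x$incidence), ncol(x$incidence)))
  invisible(x)
}

#' Adapter stub for a deposited species-list spreadsheet
#'
#' Maps a user-supplied data.frame (read from a spreadsheet by the user, e.g.
#' via an xlsx reader of their choice) onto the canonical capture schema.
#' The layout of deposited spreadsheets varies, so the column mapping is
#' explicit and validated rather than guessed; this is a convenience stub,
#' not a guaranteed parser.
#'
#' @param df the imported sheet as a data.frame.
#' @param mapping named character vector mapping canonical names
#'   (`trap_id`, `species_id`, `count`, `origin`, `guild`) to column names
#'   present in `df`.
#' @return a validated capture table.
#' @export
adapt_species_list <- function(df, mapping) {
  need <- .CAPTURE_COLUMNS
  if (!all(need %in% names(mapping))) {
    stop(sprintf("mapping must name all of: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(unname(mapping[need]), names(df))
  if (length(missing)) {
    stop(sprintf("mapped column(s) absent from sheet: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[, unname(mapping[need])]
  names(out) <- need
  validate_capture_table(out)
}
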