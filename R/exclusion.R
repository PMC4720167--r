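# Exclusion-list engine: parsing, ppm/RT clustering, cross-run merging,
# capacity capping, and instrument-import export.

entry_columns <- c("mz", "rt_start", "rt_end", "charge", "intensity",
                   "source_run", "n_members")

# Normalise a data frame of entries: add optional columns, coerce types.
as_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) > 0) {
    stopifnot(all(c("mz", "rt_start", "rt_end") %in% names(entries)))
  } else {
    for (col in c("mz", "rt_start", "rt_end")) {
      if (!col %in% names(entries)) entries[[col]] <- numeric(0)
    }
  }
  if (!"charge" %in% names(entries)) entries$charge <- NA_integer_
  if (!"intensity" %in% names(entries)) entries$intensity <- NA_real_
  if (!"source_run" %in% names(entries)) entries$source_run <- NA_character_
  if (!"n_members" %in% names(entries)) entries$n_members <- 1L
  entries$charge <- as.integer(entries$charge)
  entries$n_members <- as.integer(entries$n_members)
  if (any(entries$mz <= 0)) rlang::abort("entry m/z must be positive")
  if (any(entries$rt_start > entries$rt_end)) {
    rlang::abort("entry rt_start must not exceed rt_end")
  }
  entries[, entry_columns]
}

#' Construct an exclusion list
#'
#' An exclusion list is a tibble of precursor windows (m/z plus a closed
#' retention-time interval) carrying its matching tolerance as metadata. The
#' `n_members` column records how many original entries each row summarises,
#' so merged m/z values remain arithmetic means of the original cluster
#' members across repeated merges.
#'
#' @param entries Data frame with columns `mz`, `rt_start`, `rt_end` and
#'   optionally `charge`, `intensity`, `source_run`, `n_members`.
#' @param ppm_tolerance Matching tolerance in parts per million (default 10).
#' @param rt_pad Half-width in minutes used when windows are built from point
#'   retention times (default 2).
#' @param provenance Character vector of contributing run identifiers.
#' @return An `exclusion_list` (a tibble subclass with tolerance metadata).
#' @export
#' @examples
#' exclusion_list(data.frame(mz = 500.25, rt_start = 33.2, rt_end = 37.2))
exclusion_list <- function(entries = NULL, ppm_tolerance = 10, rt_pad = 2,
                           provenance = character()) {
  check_positive(ppm_tolerance, "ppm_tolerance")
  stopifnot(rt_pad >= 0)
  if (is.null(entries)) {
    entries <- tibble::tibble(mz = numeric(0), rt_start = numeric(0),
                              rt_end = numeric(0))
  }
  entries <- as_entries(entries)
  entries <- dplyr::arrange(entries, .data$mz, .data$rt_start)
  structure(entries,
            class = c("exclusion_list", class(tibble::tibble())),
            ppm_tolerance = ppm_tolerance, rt_pad = rt_pad,
            provenance = unique(provenance))
}

# Rebuild an exclusion_list around new entries, keeping metadata.
rebuild_list <- function(entries, template, ppm_tolerance = NULL,
                         rt_pad = NULL, provenance = NULL) {
  exclusion_list(
    entries,
    ppm_tolerance = ppm_tolerance %||% attr(template, "ppm_tolerance") %||% 10,
    rt_pad = rt_pad %||% attr(template, "rt_pad") %||% 2,
    provenance = provenance %||% attr(template, "provenance") %||% character()
  )
}

#' @export
print.exclusion_list <- function(x, ...) {
  cat(sprintf(
    "<exclusion_list> %d entries, %.4g ppm tolerance, provenance: %s\n",
    nrow(x), attr(x, "ppm_tolerance"),
    if (length(attr(x, "provenance"))) {
      paste(attr(x, "provenance"), collapse = ", ")
    } else "none"
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# One transitive-closure merge pass via union-find over mz-sorted entries.
# Returns the aggregated entries and whether anything merged.
merge_pass <- function(d, ppm, rt_gap) {
  n <- nrow(d)
  if (n < 2) return(list(d = d, merged = FALSE))
  d <- d[order(d$mz, d$rt_start), ]
  mz <- d$mz; rs <- d$rt_start; re <- d$rt_end
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol <- 1 + ppm * 1e-6
  eps_rt <- 1e-9
  merged <- FALSE
  for (i in seq_len(n - 1L)) {
    lim <- mz[i] * tol * (1 + 1e-12)
    j <- i + 1L
    while (j <= n && mz[j] <= lim) {
      if (rs[j] <= re[i] + rt_gap + eps_rt &&
          rs[i] <= re[j] + rt_gap + eps_rt) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) {
          parent[max(ri, rj)] <- min(ri, rj)
          merged <- TRUE
        }
      }
      j <- j + 1L
    }
  }
  if (!merged) return(list(d = d, merged = FALSE))
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- unname(split(seq_len(n), comp))
  w <- d$n_members
  charge <- d$charge; intensity <- d$intensity; source <- d$source_run
  out <- tibble::tibble(
    mz = vapply(groups, function(ix) sum(d$mz[ix] * w[ix]) / sum(w[ix]),
                numeric(1)),
    rt_start = vapply(groups, function(ix) min(rs[ix]), numeric(1)),
    rt_end = vapply(groups, function(ix) max(re[ix]), numeric(1)),
    charge = vapply(groups, function(ix) {
      ch <- unique(charge[ix][!is.na(charge[ix])])
      if (length(ch) == 1) ch else NA_integer_
    }, integer(1)),
    intensity = vapply(groups, function(ix) {
      it <- intensity[ix][!is.na(intensity[ix])]
      if (length(it)) max(it) else NA_real_
    }, numeric(1)),
    source_run = vapply(groups, function(ix) {
      sr <- source[ix][!is.na(source[ix])]
      if (!length(sr)) return(NA_character_)
      sr <- unique(unlist(strsplit(sr, ";", fixed = TRUE)))
      paste(sort(sr), collapse = ";")
    }, character(1)),
    n_members = vapply(groups, function(ix) sum(w[ix]), integer(1))
  )
  list(d = out, merged = TRUE)
}

#' Cluster and merge exclusion entries
#'
#' Computes the transitive closure of pairwise merges: two entries belong to
#' the same cluster when their m/z values agree within `ppm_tolerance`
#' (relative to the lower m/z of the pair) and their retention-time intervals
#' overlap or lie within `rt_gap` minutes. A merged entry takes the
#' arithmetic-mean m/z of its original members (weighted by `n_members`) and
#' the union retention-time interval. The result is canonical: sorted by
#' (m/z, rt_start) with no further merges possible.
#'
#' @param x An [exclusion_list()] or a data frame of entries.
#' @param ppm_tolerance Merge tolerance in ppm; defaults to the list's own.
#' @param rt_gap Maximum gap in minutes between RT intervals that still
#'   merges (default 0: intervals must touch or overlap).
#' @return An `exclusion_list`.
#' @export
#' @examples
#' cluster_merge(data.frame(mz = c(500.0000, 500.0040),
#'                          rt_start = c(30, 33), rt_end = c(34, 37)),
#'               ppm_tolerance = 10)
cluster_merge <- function(x, ppm_tolerance = NULL, rt_gap = 0) {
  ppm <- ppm_tolerance %||% attr(x, "ppm_tolerance") %||% 10
  check_positive(ppm, "ppm_tolerance")
  stopifnot(rt_gap >= 0)
  d <- as_entries(x)
  repeat {
    res <- merge_pass(d, ppm, rt_gap)
    d <- res$d
    if (!res$merged) break
  }
  rebuild_list(d, x, ppm_tolerance = ppm)
}

#' Merge an exclusion list with a previous list
#'
#' Union of the two entry sets re-clustered under the stricter (smaller) of
#' the two ppm tolerances, with provenance concatenated. This is the
#' cross-iteration merge used when the exclusion list from the latest run is
#' folded into the cumulative list for the next acquisition.
#'
#' @param current,previous [exclusion_list()] objects (or entry data frames).
#' @param rt_gap Passed to [cluster_merge()].
#' @return An `exclusion_list`.
#' @export
merge_lists <- function(current, previous, rt_gap = 0) {
  ppm <- min(attr(current, "ppm_tolerance") %||% 10,
             attr(previous, "ppm_tolerance") %||% 10)
  rt_pad <- min(attr(current, "rt_pad") %||% 2,
                attr(previous, "rt_pad") %||% 2)
  prov <- unique(c(attr(current, "provenance") %||% character(),
                   attr(previous, "provenance") %||% character()))
  combined <- dplyr::bind_rows(as_entries(current), as_entries(previous))
  out <- cluster_merge(combined, ppm_tolerance = ppm, rt_gap = rt_gap)
  rebuild_list(out, out, ppm_tolerance = ppm, rt_pad = rt_pad,
               provenance = prov)
}

#' Cap an exclusion list to instrument capacity
#'
#' Instrument reject tables hold a finite number of rows. The default policy
#' keeps the highest-intensity entries (ties broken by earlier `rt_start`,
#' then lower m/z); entries without a recorded intensity rank below any entry
#' that has one.
#'
#' @param x An [exclusion_list()].
#' @param max_entries Maximum entries to retain (default 2000).
#' @param policy Ranking policy; only `"intensity"` is defined.
#' @return An `exclusion_list` with at most `max_entries` rows.
#' @export
cap_list <- function(x, max_entries = 2000, policy = "intensity") {
  stopifnot(max_entries >= 0)
  if (!identical(policy, "intensity")) {
    rlang::abort(sprintf("unknown cap policy '%s'", policy))
  }
  d <- as_entries(x)
  d <- dplyr::arrange(d, dplyr::desc(.data$intensity), .data$rt_start,
                      .data$mz)
  d <- dplyr::slice_head(d, n = max_entries)
  rebuild_list(d, x)
}

#' Column dialect for exclusion-list exports
#'
#' Maps the canonical fields to the column names of a particular tabular
#' export. `rt` names a single retention-time column (expanded to a window
#' of +/- `rt_pad`); alternatively `rt_start`/`rt_end` name explicit window
#' columns. The defaults follow Proteome Discoverer-style exports.
#'
#' @param mz,rt,rt_start,rt_end,charge,intensity Column names (or `NULL`).
#' @return A named list dialect descriptor.
#' @export
exclusion_dialect <- function(mz = "m/z", rt = "RT [min]", rt_start = NULL,
                              rt_end = NULL, charge = "Charge",
                              intensity = "Intensity") {
  list(mz = mz, rt = rt, rt_start = rt_start, rt_end = rt_end,
       charge = charge, intensity = intensity)
}

numeric_column <- function(x, colname) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    rlang::abort(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                         x[bad[1]], colname, bad[1]))
  }
  out
}

#' Parse a tabular exclusion-list export
#'
#' Reads a delimited export (TSV or CSV; inferred from the delimiter in the
#' header when not given) and maps its columns through a
#' [exclusion_dialect()]. A single retention-time column becomes the window
#' \[rt - rt_pad, rt + rt_pad\].
#'
#' @param path Path to the delimited text export.
#' @param dialect Column mapping, see [exclusion_dialect()].
#' @param rt_pad Half-window in minutes applied to point retention times.
#' @param ppm_tolerance Tolerance recorded on the resulting list.
#' @param delim Field delimiter; `NULL` to infer from the header line.
#' @param source_run Optional run identifier recorded on every entry.
#' @return An `exclusion_list`.
#' @export
parse_exclusion_export <- function(path, dialect = exclusion_dialect(),
                                   rt_pad = 2, ppm_tolerance = 10,
                                   delim = NULL, source_run = NULL) {
  if (is.null(delim)) {
    first <- readr::read_lines(path, n_max = 1)
    delim <- if (length(first) && grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
  need <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("missing mandatory column '%s' (%s)", col, what))
    }
    raw[[col]]
  }
  mz <- need(dialect$mz, "m/z")
  if (is.null(mz)) rlang::abort("dialect must name an m/z column")
  mz <- numeric_column(mz, dialect$mz)
  if (!is.null(dialect$rt_start) && !is.null(dialect$rt_end)) {
    rt_start <- numeric_column(need(dialect$rt_start, "RT window start"),
                               dialect$rt_start)
    rt_end <- numeric_column(need(dialect$rt_end, "RT window end"),
                             dialect$rt_end)
  } else {
    rt <- need(dialect$rt, "retention time")
    if (is.null(rt)) rlang::abort("dialect must name an RT column")
    rt <- numeric_column(rt, dialect$rt)
    rt_start <- rt - rt_pad
    rt_end <- rt + rt_pad
  }
  charge <- if (!is.null(dialect$charge) && dialect$charge %in% names(raw)) {
    as.integer(numeric_column(raw[[dialect$charge]], dialect$charge))
  } else NA_integer_
  intensity <- if (!is.null(dialect$intensity) &&
                   dialect$intensity %in% names(raw)) {
    numeric_column(raw[[dialect$intensity]], dialect$intensity)
  } else NA_real_
  entries <- tibble::tibble(
    mz = mz, rt_start = rt_start, rt_end = rt_end, charge = charge,
    intensity = intensity,
    source_run = source_run %||% NA_character_
  )
  exclusion_list(entries, ppm_tolerance = ppm_tolerance, rt_pad = rt_pad,
                 provenance = source_run %||% character())
}

#' Export / re-import an instrument reject table
#'
#' `export_instrument_table()` writes the CSV accepted by the instrument
#' method editor: header `Mass,Start (min),End (min)`, m/z rounded to 4
#' decimals and retention times to 2. `parse_instrument_table()` reads such a
#' file back; the round trip is lossless at those precisions.
#'
#' @param x An [exclusion_list()].
#' @param path Destination (source) file path.
#' @param ppm_tolerance,rt_pad Metadata recorded when re-importing.
#' @return `export_instrument_table()` returns `path` invisibly;
#'   `parse_instrument_table()` returns an `exclusion_list`.
#' @export
export_instrument_table <- function(x, path) {
  d <- as_entries(x)
  lines <- c("Mass,Start (min),End (min)",
             if (nrow(d)) sprintf("%.4f,%.2f,%.2f", d$mz, d$rt_start,
                                  d$rt_end))
  tryCatch(readr::write_lines(lines, path),
           error = function(e) {
             rlang::abort(sprintf("cannot write instrument table to '%s': %s",
                                  path, conditionMessage(e)))
           })
  invisible(path)
}

#' @rdname export_instrument_table
#' @export
parse_instrument_table <- function(path, ppm_tolerance = 10, rt_pad = 2) {
  parse_exclusion_export(
    path,
    dialect = exclusion_dialect(mz = "Mass", rt = NULL,
                                rt_start = "Start (min)",
                                rt_end = "End (min)",
                                charge = NULL, intensity = NULL),
    rt_pad = rt_pad, ppm_tolerance = ppm_tolerance, delim = ","
  )
}

#' Round-trip TSV format preserving charge, intensity and provenance
#'
#' Richer sibling of the instrument CSV: all entry columns at full precision
#' plus the list metadata in `#`-prefixed header lines.
#'
#' @param x An [exclusion_list()].
#' @param path File path.
#' @return `write_exclusion_tsv()` returns `path` invisibly;
#'   `read_exclusion_tsv()` an `exclusion_list`.
#' @export
write_exclusion_tsv <- function(x, path) {
  d <- as_entries(x)
  header <- c(
    sprintf("# ppm_tolerance: %.10g", attr(x, "ppm_tolerance") %||% 10),
    sprintf("# rt_pad: %.10g", attr(x, "rt_pad") %||% 2),
    sprintf("# provenance: %s",
            paste(attr(x, "provenance") %||% character(), collapse = ";"))
  )
  readr::write_lines(header, path)
  readr::write_tsv(d, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_exclusion_tsv
#' @export
read_exclusion_tsv <- function(path) {
  head_lines <- readr::read_lines(path, n_max = 3)
  meta <- function(key, default) {
    ln <- grep(sprintf("^# %s:", key), head_lines, value = TRUE)
    if (!length(ln)) return(default)
    val <- trimws(sub(sprintf("^# %s:", key), "", ln[1]))
    val
  }
  ppm <- as.numeric(meta("ppm_tolerance", "10"))
  rt_pad <- as.numeric(meta("rt_pad", "2"))
  prov <- meta("provenance", "")
  prov <- if (nzchar(prov)) strsplit(prov, ";", fixed = TRUE)[[1]]
          else character()
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  exclusion_list(d, ppm_tolerance = ppm, rt_pad = rt_pad, provenance = prov)
}
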