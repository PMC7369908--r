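#' Interaction-energy time series
#'
#' Container for one per-frame ligand--surrounding interaction-energy trace:
#' a single (state, component, group) identity for one ligand. `group` is
#' `"surroundings"` for whole-environment totals, or a residue/ion label
#' (e.g. `"His208"`, `"Cu_B"`) for decomposition series.
#'
#' @param ligand_id Ligand identifier (scalar character).
#' @param state `"bound"` (ligand in the solvated complex) or `"free"`
#'   (ligand alone in solvent).
#' @param component `"electrostatic"` or `"vdw"`.
#' @param group Interaction partner label; default `"surroundings"`.
#' @param times Numeric vector of time points (ps), strictly increasing.
#' @param values Numeric vector of energies (kcal/mol), same length as
#'   `times`, all finite.
#' @return An object of class `energy_series`.
#' @export
energy_series <- function(ligand_id, state, component, times, values,
                          group = "surroundings") {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1L)
  state <- match.arg(state, c("bound", "free"))
  component <- match.arg(component, c("electrostatic", "vdw"))
  stopifnot(is.character(group), length(group) == 1L)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 1L || length(times) != length(values))
    stop("'times' and 'values' must be non-empty and of equal length")
  if (any(!is.finite(values)))
    stop("all energy values must be finite")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be finite and strictly increasing")
  structure(
    list(ligand_id = ligand_id, state = state, component = component,
         group = group, times = times, values = values),
    class = "energy_series"
  )
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %s | %s | %s | %s\n", x$ligand_id, x$state,
              x$component, x$group))
  cat(sprintf("  %d frames, t = [%g, %g] ps, mean %.3f kcal/mol\n",
              length(x$values), x$times[1L], x$times[length(x$times)],
              mean(x$values)))
  invisible(x)
}

#' @export
length.energy_series <- function(x) length(x$values)

#' Restrict a series to an analysis window
#'
#' Keeps frames with `t_start <= time <= t_end`. MD production runs are
#' typically analysed over a late, equilibrated window (e.g. the last 4 ns
#' of a 10 ns trajectory); windowing is left to the caller and defaults to
#' the full series.
#'
#' @param series An [energy_series()].
#' @param t_start,t_end Window bounds in ps (`NULL` = unbounded).
#' @return The windowed `energy_series`.
#' @export
window_series <- function(series, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(series, "energy_series"))
  keep <- rep(TRUE, length(series$times))
  if (!is.null(t_start)) keep <- keep & series$times >= t_start
  if (!is.null(t_end)) keep <- keep & series$times <= t_end
  if (!any(keep))
    stop("empty analysis window: no frames in [t_start, t_end]")
  energy_series(series$ligand_id, series$state, series$component,
                series$times[keep], series$values[keep], series$group)
}

# identity key used to partition table rows into series
series_key <- function(ligand_id, state, component, group) {
  paste(ligand_id, state, component, group, sep = "|")
}

#' Read an interaction-energy table
#'
#' Reads a delimited text file of per-frame interaction energies into a list
#' of [energy_series()] objects, one per unique
#' (ligand_id, state, component, group) identity. The dialect is UTF-8,
#' comma- or tab-delimited (auto-detected from the header line), `#`
#' comment lines, and requires the columns `ligand_id`, `state`,
#' `component`, `group`, `time_ps`, `energy_kcal`.
#'
#' @param path Path to the energy table.
#' @param delim Field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @return Named list of `energy_series` (names are the
#'   `ligand_id|state|component|group` identity keys), row order within a
#'   series preserved after sorting by time.
#' @export
read_energy_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  body <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(body)) stop("format error: empty energy table")
  header_line <- lines[body][1L]
  if (is.null(delim))
    delim <- if (grepl("\t", header_line)) "\t" else ","
  tab <- utils::read.table(text = lines[body], header = TRUE, sep = delim,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, quote = "\"")
  required <- c("ligand_id", "state", "component", "group", "time_ps",
                "energy_kcal")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))

  # map data rows back to file line numbers for parse diagnostics
  line_no <- which(body)[-1L]
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("parse error: non-finite %s at line %d ('%s')",
                   col, line_no[bad[1L]], tab[[col]][bad[1L]]))
    v
  }
  time_ps <- num("time_ps")
  energy <- num("energy_kcal")

  key <- series_key(tab$ligand_id, tab$state, tab$component, tab$group)
  if (anyDuplicated(paste(key, time_ps)))
    stop("validation error: duplicate (identity, time) row(s)")

  idx <- split(seq_len(nrow(tab)), key)
  out <- lapply(idx, function(i) {
    i <- i[order(time_ps[i])]
    energy_series(tab$ligand_id[i[1L]], tab$state[i[1L]],
                  tab$component[i[1L]], time_ps[i], energy[i],
                  tab$group[i[1L]])
  })
  out[order(names(out))]
}

#' Write an interaction-energy table
#'
#' Inverse of [read_energy_table()]: serializes a collection of
#' [energy_series()] to the delimited dialect (comma-separated).
#'
#' @param series_list List of `energy_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(series_list, path) {
  stopifnot(length(series_list) >= 1L)
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(ligand_id = s$ligand_id, state = s$state,
               component = s$component, group = s$group,
               time_ps = s$times, energy_kcal = s$values)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Block-averaged mean and standard error
#'
#' Splits a (generally autocorrelated) energy series into `n_blocks`
#' contiguous, near-equal blocks and estimates the uncertainty of the time
#' average as the standard deviation of the block means divided by
#' `sqrt(n_blocks)`. The mean itself is the grand mean over all frames.
#' With `n_blocks = 1` no spread is measurable; the summary then carries
#' `sem = 0` and a `degenerate` flag, and a warning is raised.
#'
#' @param series An [energy_series()].
#' @param n_blocks Number of blocks (default 5, a common MD convention).
#' @param t_start,t_end Optional analysis window (ps), see
#'   [window_series()].
#' @return An `energy_summary`: list with `mean`, `sem`, `n_frames`,
#'   `n_blocks`, `degenerate`, plus the series identity fields.
#' @export
block_average <- function(series, n_blocks = 5L, t_start = NULL,
                          t_end = NULL) {
  stopifnot(inherits(series, "energy_series"))
  series <- window_series(series, t_start, t_end)
  n <- length(series$values)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("'n_blocks' must be >= 1")
  if (n_blocks > n)
    stop("'n_blocks' (", n_blocks, ") exceeds number of frames (", n, ")")
  degenerate <- n_blocks == 1L
  if (degenerate) {
    warning("n_blocks = 1: block spread undefined, reporting sem = 0")
    sem <- 0
  } else {
    blocks <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
    bmeans <- vapply(split(series$values, blocks), mean, numeric(1))
    sem <- stats::sd(bmeans) / sqrt(n_blocks)
  }
  structure(
    list(ligand_id = series$ligand_id, state = series$state,
         component = series$component, group = series$group,
         mean = mean(series$values), sem = sem, n_frames = n,
         n_blocks = n_blocks, degenerate = degenerate),
    class = "energy_summary"
  )
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf("<energy_summary> %s | %s | %s | %s: %.3f +/- %.3f kcal/mol (%d frames, %d blocks)\n",
              x$ligand_id, x$state, x$component, x$group, x$mean, x$sem,
              x$n_frames, x$n_blocks))
  invisible(x)
}

#' Write energy summaries as delimited text
#'
#' Columns: `ligand_id,state,component,group,mean,sem,n_frames,n_blocks`,
#' numeric fields fixed at 6 decimal places so a write/read/write cycle is
#' byte-identical.
#'
#' @param summaries List of `energy_summary` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (length(summaries) < 1L) stop("empty summary collection")
  stopifnot(all(vapply(summaries, inherits, logical(1), "energy_summary")))
  rows <- vapply(summaries, function(s) {
    sprintf("%s,%s,%s,%s,%.6f,%.6f,%d,%d", s$ligand_id, s$state,
            s$component, s$group, s$mean, s$sem, s$n_frames, s$n_blocks)
  }, character(1))
  con <- file(path, open = "wb")  # fixed EOL for byte-identical round trips
  on.exit(close(con))
  writeLines(c("ligand_id,state,component,group,mean,sem,n_frames,n_blocks",
               rows), con, sep = "\n")
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path Input path.
#' @return List of `energy_summary` objects (degenerate flag inferred from
#'   `n_blocks`).
#' @export
read_summary_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ligand_id", "state", "component", "group", "mean", "sem",
                "n_frames", "n_blocks")
  if (!all(required %in% names(tab)))
    stop("format error: missing column(s) ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    structure(
      list(ligand_id = tab$ligand_id[i], state = tab$state[i],
           component = tab$component[i], group = tab$group[i],
           mean = tab$mean[i], sem = tab$sem[i],
           n_frames = tab$n_frames[i], n_blocks = tab$n_blocks[i],
           degenerate = tab$n_blocks[i] == 1L),
      class = "energy_summary"
    )
  })
}
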