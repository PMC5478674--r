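#' Write and read grid snapshots
#'
#' Serialises a grid state as a plain CSV in long format (one row per
#' cell: `row`, `col`, `sand`, `base`, `species_code`, `growth`, `age`)
#' preceded by `#`-prefixed metadata lines recording the geometry, clock
#' and boundary mode. Species codes: 0 bare, 1 grass, 2 shrub, 3 tree.
#'
#' @param grid an `ecodune_grid`.
#' @param path file path.
#' @param config configuration used when re-reading (geometry defaults).
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   an `ecodune_grid`.
#' @export
write_snapshot <- function(grid, path) {
  meta <- c(
    sprintf("# width: %d", grid$width),
    sprintf("# height: %d", grid$height),
    sprintf("# cell_size: %g", grid$cell_size),
    sprintf("# slab_height: %g", grid$slab_height),
    sprintf("# boundary: %s", grid$boundary),
    sprintf("# year: %d", grid$clock$year),
    sprintf("# season: %s", grid$clock$season)
  )
  idx <- expand.grid(row = seq_len(grid$height), col = seq_len(grid$width))
  df <- data.frame(idx,
                   sand = as.vector(grid$sand),
                   base = as.vector(grid$base),
                   species_code = as.vector(grid$species),
                   growth = as.vector(grid$growth),
                   age = as.vector(grid$age))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, config = default_config()) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# *", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  h <- as.integer(meta$height); w <- as.integer(meta$width)
  ord <- order(df$col, df$row)
  df <- df[ord, ]
  g <- init_grid(w, h, 0, config = config,
                 start_year = as.integer(meta$year),
                 start_season = meta$season)
  g$cell_size <- as.numeric(meta$cell_size)
  g$slab_height <- as.numeric(meta$slab_height)
  g$boundary <- meta$boundary
  g$sand <- matrix(as.integer(df$sand), h, w)
  g$base <- matrix(df$base, h, w)
  g$species <- matrix(as.integer(df$species_code), h, w)
  g$growth <- matrix(df$growth, h, w)
  g$age <- matrix(as.integer(df$age), h, w)
  g$sand_ref <- g$sand
  g
}
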