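#' Landmark configurations and datasets
#'
#' A *landmark configuration* is one specimen's ordered set of K
#' two-dimensional landmarks (here, wing-vein junctions and termini;
#' K = 14 in the study design this package emulates) plus identifying
#' metadata. Landmark order is semantic: landmark i must be the same
#' anatomical point on every specimen. A *landmark dataset* bundles N
#' configurations sharing a common K with per-specimen metadata
#' (`sex`, `site`) that defines the analysis groups.
#'
#' @param specimen_id character scalar identifying the specimen.
#' @param coords numeric K x 2 matrix of landmark coordinates (mm).
#' @param sex,site optional metadata labels.
#' @param scale mm-per-pixel factor already applied to `coords`
#'   (recorded for provenance; default 1).
#' @return `landmark_config()` returns an object of class
#'   `"landmark_config"`: a list with elements `specimen_id`, `coords`,
#'   `sex`, `site`, `scale`.
#' @export
landmark_config <- function(specimen_id, coords, sex = NA_character_,
                            site = NA_character_, scale = 1) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stopf("landmark coordinates must be 2-D (got %d columns)", ncol(coords))
  if (!all(is.finite(coords)))
    stopf("specimen '%s': non-finite landmark coordinates", specimen_id)
  storage.mode(coords) <- "double"
  structure(
    list(specimen_id = as.character(specimen_id), coords = coords,
         sex = sex, site = site, scale = scale),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks, sex=%s, site=%s\n",
              x$specimen_id, nrow(x$coords), x$sex, x$site))
  invisible(x)
}

#' Assemble a landmark dataset
#'
#' Bundles a list of [landmark_config()] objects into an N-specimen
#' dataset with a K x 2 x N coordinate array and a metadata data frame.
#' All configurations must share the same landmark count K and carry
#' non-missing `sex` and `site` labels (the default grouping is
#' site crossed with sex).
#'
#' @param configs list of `landmark_config` objects.
#' @return An object of class `"landmark_dataset"`: a list with
#'   `coords` (K x 2 x N array, specimen ids on the third dimension)
#'   and `meta` (data frame with columns `specimen_id`, `sex`, `site`).
#' @export
landmark_dataset <- function(configs) {
  if (length(configs) == 0L) stopf("dataset must contain at least one specimen")
  ks <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(ks)) != 1L)
    stopf("all specimens must share the same landmark count (found: %s)",
          paste(unique(ks), collapse = ", "))
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  if (anyDuplicated(ids))
    stopf("duplicated specimen ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  k <- ks[1]
  arr <- array(NA_real_, dim = c(k, 2L, length(configs)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$coords
  meta <- data.frame(
    specimen_id = ids,
    sex  = vapply(configs, function(cf) as.character(cf$sex),  character(1)),
    site = vapply(configs, function(cf) as.character(cf$site), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(coords = arr, meta = meta), class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<landmark_dataset> %d specimens x %d landmarks\n", d[3], d[1]))
  print(group_counts(x))
  invisible(x)
}

n_specimens <- function(dataset) dim(dataset$coords)[3]
n_landmarks <- function(dataset) dim(dataset$coords)[1]

#' Group count table
#'
#' Cross-tabulates specimens by sex and site, with row/column totals —
#' the usual "specimens analyzed" layout of a morphometric survey.
#'
#' @param dataset a `landmark_dataset`.
#' @return integer matrix, sexes x sites, with marginal totals appended.
#' @export
group_counts <- function(dataset) {
  tab <- table(dataset$meta$sex, dataset$meta$site)
  out <- cbind(Total = rowSums(tab), unclass(tab))
  rbind(out, Total = colSums(out))
}

# ---- TPS interchange format ------------------------------------------------

#' Read a TPS landmark file
#'
#' Parses the TPS landmark dialect (`LM=` record headers followed by one
#' coordinate pair per line, then `ID=`, and optionally `IMAGE=`,
#' `SCALE=`, `COMMENT=` keys). Coordinates are multiplied by `SCALE=`
#' when present, so returned configurations are in physical units.
#' Unknown keys are skipped with a warning (tolerant reader). Only 2-D
#' coordinates are accepted: a third column is an error. Coordinates are
#' taken verbatim in a Cartesian y-up convention; no image-row flip is
#' applied (see the package vignette — files digitized y-down differ by
#' a reflection, which proper-rotation superimposition does not absorb).
#'
#' @param path path to a TPS file.
#' @return list of [landmark_config()] objects, in file order. Sex and
#'   site are `NA`; attach metadata with [read_dataset()].
#' @seealso [write_tps()], [read_dataset()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stopf("TPS file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n <- length(lines)
  skip_blank <- function(j) {
    while (j <= n && grepl("^\\s*$", lines[j])) j <- j + 1L
    j
  }
  i <- skip_blank(i)
  while (i <= n) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^\\s*LM\\s*=\\s*([0-9]+)\\s*$", ln,
                                ignore.case = TRUE))[[1]]
    if (length(m) == 0L)
      stopf("line %d: expected an 'LM=' record header, got '%s'", i, ln)
    k_decl <- as.integer(m[2])
    header_line <- i
    i <- i + 1L
    coords <- matrix(NA_real_, nrow = k_decl, ncol = 2)
    got <- 0L
    while (got < k_decl && i <= n) {
      ln <- trimws(lines[i])
      if (grepl("^[A-Za-z]+\\s*=", ln) || grepl("^\\s*$", ln)) break
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 2L)
        stopf("line %d: expected 2 coordinates per landmark, got %d",
              i, length(parts))
      xy <- suppressWarnings(as.numeric(parts))
      if (any(is.na(xy)))
        stopf("line %d: non-numeric coordinate '%s'", i, lines[i])
      got <- got + 1L
      coords[got, ] <- xy
      i <- i + 1L
    }
    # trailing keys for this record
    id <- NA_character_; scale <- NA_real_
    repeat {
      i <- skip_blank(i)
      if (i > n) break
      ln <- trimws(lines[i])
      if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) break
      km <- regmatches(ln, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(km) == 0L)
        stopf("line %d: unexpected content '%s' (coordinates beyond LM=%d?)",
              i, ln, k_decl)
      key <- toupper(km[2]); val <- trimws(km[3])
      if (key == "ID") id <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale)) stopf("line %d: non-numeric SCALE '%s'", i, val)
      } else if (!key %in% c("IMAGE", "COMMENT")) {
        warnf("line %d: ignoring unknown TPS key '%s='", i, key)
      }
      i <- i + 1L
    }
    rec_name <- if (is.na(id)) sprintf("record starting at line %d", header_line)
                else sprintf("record '%s'", id)
    if (got < k_decl)
      stopf("%s declares LM=%d but lists %d coordinate pairs",
            rec_name, k_decl, got)
    if (is.na(id)) id <- sprintf("record_%d", length(recs) + 1L)
    if (!is.na(scale)) coords <- coords * scale
    recs[[length(recs) + 1L]] <-
      landmark_config(id, coords, scale = if (is.na(scale)) 1 else scale)
  }
  if (length(recs) == 0L) stopf("no TPS records found in %s", path)
  recs
}

#' Write a TPS landmark file
#'
#' One `LM=`/coordinates/`ID=` record per configuration, in sequence
#' order. Coordinates are written at full double precision so a
#' read/write round trip is lossless well below 1e-9.
#'
#' @param configs non-empty list of `landmark_config` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stopf("cannot write an empty set of configurations")
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$coords)),
      sprintf("%.12g %.12g", cf$coords[, 1], cf$coords[, 2]),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read landmarks plus specimen metadata into a grouped dataset
#'
#' Joins a TPS coordinate file with a comma-separated metadata table
#' (UTF-8, header row required, columns `specimen_id`, `sex`, `site`).
#' The join must be one-to-one: every TPS record id appears exactly once
#' in the metadata and vice versa; offenders on either side are listed
#' in the error.
#'
#' @param coords path to a TPS landmark file.
#' @param metadata path to the metadata CSV.
#' @return a [landmark_dataset()].
#' @export
read_dataset <- function(coords, metadata) {
  configs <- read_tps(coords)
  meta <- utils::read.csv(metadata, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  need <- c("specimen_id", "sex", "site")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L)
    stopf("metadata lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyDuplicated(meta$specimen_id))
    stopf("metadata has duplicated specimen_id(s): %s",
          paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
                collapse = ", "))
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  no_meta <- setdiff(ids, meta$specimen_id)
  no_tps  <- setdiff(meta$specimen_id, ids)
  if (length(no_meta) || length(no_tps))
    stopf(paste0("specimen_id join mismatch",
                 if (length(no_meta)) sprintf("; in TPS but not metadata: %s",
                                              paste(no_meta, collapse = ", ")),
                 if (length(no_tps)) sprintf("; in metadata but not TPS: %s",
                                             paste(no_tps, collapse = ", "))))
  rows <- match(ids, meta$specimen_id)
  for (i in seq_along(configs)) {
    configs[[i]]$sex  <- meta$sex[rows[i]]
    configs[[i]]$site <- meta$site[rows[i]]
  }
  landmark_dataset(configs)
}
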