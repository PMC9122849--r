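#' @keywords internal
"_PACKAGE"

#' Land-cover classes used throughout the package
#'
#' The six mapped land-cover classes plus `"other"`, which absorbs any
#' landscape area not assigned to a mapped class so that composition
#' proportions always sum to one.
#'
#' @return Character vector of class names, `"other"` last.
#' @export
landcover_classes <- function() {
  c("arable", "permanent_crop", "forest", "woody_snh",
    "herbaceous_snh", "urban", "other")
}

#' Flowering periods recognised by the index
#'
#' @return Character vector: `"preceding"`, `"synchronous"`, `"pooled"`.
#' @export
fai_periods <- function() c("preceding", "synchronous", "pooled")

# -- internal validation helpers ----------------------------------------------

stop_rows <- function(msg, rows) {
  rows <- utils::head(rows, 5L)
  stop(msg, " (row", if (length(rows) > 1L) "s", " ",
       paste(rows, collapse = ", "), ")", call. = FALSE)
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("table '", table, "' is missing required column",
         if (length(missing) > 1L) "s", ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Validate a pollen-diet table
#'
#' Columns: `pollen_type`, `period`, `volume` (relative pollen volume,
#' unitless, non-negative). `(pollen_type, period)` pairs must be unique.
#' Period membership of a pollen type is taken from the presence of its row,
#' not from its volume, so a type can be listed for a period with volume 0.
#'
#' @param diet data.frame.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_diet <- function(diet) {
  check_columns(diet, c("pollen_type", "period", "volume"), "diet")
  diet$pollen_type <- as.character(diet$pollen_type)
  diet$period <- as.character(diet$period)
  bad <- which(!diet$period %in% setdiff(fai_periods(), "pooled"))
  if (length(bad) > 0L) {
    stop_rows(paste0("diet: unknown period '", diet$period[bad[1L]],
                     "'; expected one of ",
                     paste(setdiff(fai_periods(), "pooled"), collapse = ", ")),
              bad)
  }
  if (!is.numeric(diet$volume)) stop("diet: 'volume' must be numeric", call. = FALSE)
  neg <- which(is.na(diet$volume) | diet$volume < 0)
  if (length(neg) > 0L) stop_rows("diet: negative or missing volume", neg)
  dup <- which(duplicated(diet[, c("pollen_type", "period")]))
  if (length(dup) > 0L) {
    stop_rows(paste0("diet: duplicate (pollen_type, period) key '",
                     diet$pollen_type[dup[1L]], "', '", diet$period[dup[1L]], "'"),
              dup)
  }
  diet
}

#' Validate a plant annotation table
#'
#' Columns: `species`, `pollen_type`, `growth_form` (`woody`/`herbaceous`),
#' `origin` (`wild`/`cultivated`). Each species maps to exactly one pollen
#' type.
#'
#' @param plants data.frame.
#' @return Validated data.frame.
#' @export
validate_plants <- function(plants) {
  check_columns(plants, c("species", "pollen_type", "growth_form", "origin"),
                "plants")
  for (col in c("species", "pollen_type", "growth_form", "origin")) {
    plants[[col]] <- as.character(plants[[col]])
    blank <- which(is.na(plants[[col]]) | !nzchar(plants[[col]]))
    if (length(blank) > 0L) stop_rows(paste0("plants: empty '", col, "'"), blank)
  }
  dup <- which(duplicated(plants$species))
  if (length(dup) > 0L) {
    stop_rows(paste0("plants: species '", plants$species[dup[1L]],
                     "' annotated more than once"), dup)
  }
  bad <- which(!plants$growth_form %in% c("woody", "herbaceous"))
  if (length(bad) > 0L) {
    stop_rows("plants: growth_form must be 'woody' or 'herbaceous'", bad)
  }
  bad <- which(!plants$origin %in% c("wild", "cultivated"))
  if (length(bad) > 0L) {
    stop_rows("plants: origin must be 'wild' or 'cultivated'", bad)
  }
  plants
}

#' Validate a plant-cover table
#'
#' Columns: `landscape_id`, `species`, `cover_m2` (area in square meters,
#' non-negative). Every species must be present in the annotation table.
#'
#' @param cover data.frame.
#' @param plants Validated annotation table.
#' @return Validated data.frame.
#' @export
validate_cover <- function(cover, plants) {
  check_columns(cover, c("landscape_id", "species", "cover_m2"), "cover")
  cover$landscape_id <- as.character(cover$landscape_id)
  cover$species <- as.character(cover$species)
  if (!is.numeric(cover$cover_m2)) stop("cover: 'cover_m2' must be numeric", call. = FALSE)
  neg <- which(is.na(cover$cover_m2) | cover$cover_m2 < 0)
  if (length(neg) > 0L) stop_rows("cover: negative or missing cover_m2", neg)
  unknown <- setdiff(unique(cover$species), plants$species)
  if (length(unknown) > 0L) {
    stop("cover: species absent from the annotation table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cover
}

#' Validate a tabular land-cover composition table
#'
#' Long format with columns `landscape_id`, `class`, `proportion`. Classes
#' must come from [landcover_classes()]; per landscape the proportions of the
#' mapped classes must not exceed 1 (any shortfall is assigned to `"other"`).
#'
#' @param landcover data.frame.
#' @return Validated data.frame.
#' @export
validate_landcover <- function(landcover) {
  check_columns(landcover, c("landscape_id", "class", "proportion"), "landcover")
  landcover$landscape_id <- as.character(landcover$landscape_id)
  landcover$class <- as.character(landcover$class)
  bad <- which(!landcover$class %in% landcover_classes())
  if (length(bad) > 0L) {
    stop_rows(paste0("landcover: unknown class '", landcover$class[bad[1L]], "'"),
              bad)
  }
  if (!is.numeric(landcover$proportion)) {
    stop("landcover: 'proportion' must be numeric", call. = FALSE)
  }
  out <- which(is.na(landcover$proportion) | landcover$proportion < 0 |
                 landcover$proportion > 1)
  if (length(out) > 0L) stop_rows("landcover: proportion outside [0, 1]", out)
  dup <- which(duplicated(landcover[, c("landscape_id", "class")]))
  if (length(dup) > 0L) stop_rows("landcover: duplicate (landscape_id, class)", dup)
  landcover
}

#' Validate a distances table
#'
#' Columns: `landscape_id`, `dist_forest_m`, `dist_urban_m` (meters, >= 0):
#' Euclidean distance from the landscape center to the nearest forest and
#' urban patch.
#'
#' @param distances data.frame.
#' @return Validated data.frame.
#' @export
validate_distances <- function(distances) {
  check_columns(distances, c("landscape_id", "dist_forest_m", "dist_urban_m"),
                "distances")
  distances$landscape_id <- as.character(distances$landscape_id)
  for (col in c("dist_forest_m", "dist_urban_m")) {
    if (!is.numeric(distances[[col]])) {
      stop("distances: '", col, "' must be numeric", call. = FALSE)
    }
    neg <- which(is.na(distances[[col]]) | distances[[col]] < 0)
    if (length(neg) > 0L) stop_rows(paste0("distances: negative or missing ", col), neg)
  }
  dup <- which(duplicated(distances$landscape_id))
  if (length(dup) > 0L) stop_rows("distances: duplicate landscape_id", dup)
  distances
}

#' Validate a seed-set table
#'
#' Columns: `landscape_id`, `pod_id`, `seeds` (non-negative integer count of
#' developed seeds per harvested pod).
#'
#' @param seedset data.frame.
#' @return Validated data.frame.
#' @export
validate_seedset <- function(seedset) {
  check_columns(seedset, c("landscape_id", "pod_id", "seeds"), "seedset")
  seedset$landscape_id <- as.character(seedset$landscape_id)
  seedset$pod_id <- as.character(seedset$pod_id)
  if (!is.numeric(seedset$seeds)) stop("seedset: 'seeds' must be numeric", call. = FALSE)
  bad <- which(is.na(seedset$seeds) | seedset$seeds < 0 |
                 seedset$seeds != round(seedset$seeds))
  if (length(bad) > 0L) stop_rows("seedset: seeds must be non-negative integers", bad)
  seedset$seeds <- as.integer(round(seedset$seeds))
  dup <- which(duplicated(seedset[, c("landscape_id", "pod_id")]))
  if (length(dup) > 0L) stop_rows("seedset: duplicate (landscape_id, pod_id)", dup)
  seedset
}

#' Assemble and validate an input bundle from in-memory tables
#'
#' @param diet,plants,cover,landcover,distances,seedset data.frames with the
#'   schemas documented in the `validate_*` functions.
#' @return A list of class `fai_bundle` with the validated tables and the
#'   vector of landscape ids (union over cover, landcover and seedset).
#' @export
as_bundle <- function(diet, plants, cover, landcover, distances, seedset) {
  plants <- validate_plants(plants)
  bundle <- list(
    diet = validate_diet(diet),
    plants = plants,
    cover = validate_cover(cover, plants),
    landcover = validate_landcover(landcover),
    distances = validate_distances(distances),
    seedset = validate_seedset(seedset)
  )
  bundle$landscape_ids <- sort(unique(c(
    bundle$cover$landscape_id, bundle$landcover$landscape_id,
    bundle$seedset$landscape_id
  )))
  unmapped <- setdiff(unique(bundle$diet$pollen_type),
                      unique(plants$pollen_type))
  if (length(unmapped) > 0L) {
    message("diet pollen types with no mapped plant species (treated as ",
            "unmapped): ", paste(unmapped, collapse = ", "))
  }
  structure(bundle, class = "fai_bundle")
}

#' Load and validate all input tables from a directory of CSV files
#'
#' Expects `diet.csv`, `plants.csv`, `cover.csv`, `landcover.csv`,
#' `distances.csv` and `seedset.csv` (schemas in the `validate_*` functions;
#' lines starting with `#` are treated as comments).
#'
#' @param dir Directory containing the six CSV files.
#' @return A validated `fai_bundle`; see [as_bundle()].
#' @export
load_tables <- function(dir) {
  files <- c(diet = "diet.csv", plants = "plants.csv", cover = "cover.csv",
             landcover = "landcover.csv", distances = "distances.csv",
             seedset = "seedset.csv")
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("missing input file(s) in '", dir, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tabs <- lapply(paths, utils::read.csv, comment.char = "#",
                 stringsAsFactors = FALSE)
  names(tabs) <- names(files)
  as_bundle(tabs$diet, tabs$plants, tabs$cover, tabs$landcover,
            tabs$distances, tabs$seedset)
}

#' Write an input bundle to a directory of CSV files
#'
#' Inverse of [load_tables()]. A comment header recording the generating seed
#' (if the bundle carries one) is prepended to every file.
#'
#' @param bundle `fai_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- if (!is.null(attr(bundle, "seed"))) {
    paste0("# generated by floravail::generate(), seed = ", attr(bundle, "seed"))
  }
  for (tab in c("diet", "plants", "cover", "landcover", "distances", "seedset")) {
    path <- file.path(dir, paste0(tab, ".csv"))
    con <- file(path, "w")
    if (!is.null(header)) writeLines(header, con)
    utils::write.csv(bundle[[tab]], con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Landscape composition in wide form
#'
#' Converts the long land-cover table plus the distances table into one row
#' per landscape with a column per class (missing classes 0, any shortfall
#' from 1 assigned to `"other"`) and the two distances. Mapped proportions
#' exceeding 1 by more than `tol` are an error.
#'
#' @param landcover Validated long land-cover table.
#' @param distances Validated distances table.
#' @param tol Tolerance on the unit-sum constraint (default `1e-9`).
#' @return data.frame: `landscape_id`, one column per [landcover_classes()],
#'   `dist_forest_m`, `dist_urban_m`.
#' @export
landscape_composition <- function(landcover, distances, tol = 1e-9) {
  landcover <- validate_landcover(landcover)
  distances <- validate_distances(distances)
  ids <- sort(unique(landcover$landscape_id))
  classes <- landcover_classes()
  wide <- matrix(0, nrow = length(ids), ncol = length(classes),
                 dimnames = list(ids, classes))
  idx <- cbind(match(landcover$landscape_id, ids),
               match(landcover$class, classes))
  wide[idx] <- landcover$proportion
  mapped <- rowSums(wide[, setdiff(classes, "other"), drop = FALSE])
  over <- which(mapped + wide[, "other"] > 1 + tol)
  if (length(over) > 0L) {
    stop("landcover: proportions exceed 1 for landscape(s) ",
         paste(ids[over], collapse = ", "), call. = FALSE)
  }
  wide[, "other"] <- pmax(0, 1 - mapped)
  miss <- setdiff(ids, distances$landscape_id)
  if (length(miss) > 0L) {
    stop("distances: no row for landscape(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- distances[match(ids, distances$landscape_id), ]
  data.frame(landscape_id = ids, wide,
             dist_forest_m = d$dist_forest_m, dist_urban_m = d$dist_urban_m,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean developed seeds per pod, per landscape
#'
#' Pollination success is the mean number of developed seeds over harvested
#' pods. Following the harvest definition (pods with at least one developed
#' seed), zero-seed pods are excluded by default; `include_zero_pods = TRUE`
#' keeps them. Landscapes with no qualifying pod get `NA` and are listed in
#' the `"missing"` attribute.
#'
#' @param seedset Validated seed-set table.
#' @param include_zero_pods Include pods with 0 developed seeds (default
#'   `FALSE`).
#' @return data.frame: `landscape_id`, `n_pods`, `seeds_per_pod`; attribute
#'   `"missing"` lists landscapes with no qualifying pods.
#' @export
seeds_per_pod <- function(seedset, include_zero_pods = FALSE) {
  seedset <- validate_seedset(seedset)
  ids <- sort(unique(seedset$landscape_id))
  keep <- if (include_zero_pods) rep(TRUE, nrow(seedset)) else seedset$seeds >= 1L
  s <- seedset[keep, ]
  n_pods <- as.integer(table(factor(s$landscape_id, levels = ids)))
  mean_seeds <- tapply(s$seeds, factor(s$landscape_id, levels = ids), mean)
  out <- data.frame(landscape_id = ids, n_pods = n_pods,
                    seeds_per_pod = as.numeric(mean_seeds),
                    row.names = NULL, stringsAsFactors = FALSE)
  missing <- out$landscape_id[out$n_pods == 0L]
  if (length(missing) > 0L) {
    warning("no pods with >= 1 developed seed in landscape(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(out, "missing") <- missing
  out
}

#' Read a minimal key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (line in lines) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("config: cannot parse line '", line, "'", call. = FALSE)
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
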