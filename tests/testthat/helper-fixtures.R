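# In-code fixtures shared across test files.

# minimal valid tables (two landscapes, two pollen types)
tiny_tables <- function() {
  list(
    diet = data.frame(pollen_type = c("p1", "p2"), period = "preceding",
                      volume = c(80, 20), stringsAsFactors = FALSE),
    plants = data.frame(species = c("sp1", "sp2"),
                        pollen_type = c("p1", "p2"),
                        growth_form = c("woody", "herbaceous"),
                        origin = c("wild", "cultivated"),
                        stringsAsFactors = FALSE),
    cover = data.frame(landscape_id = c("L1", "L2", "L1", "L2"),
                       species = c("sp1", "sp1", "sp2", "sp2"),
                       cover_m2 = c(10, 10, 0, 20), stringsAsFactors = FALSE),
    landcover = data.frame(landscape_id = rep(c("L1", "L2"), each = 2L),
                           class = rep(c("arable", "urban"), 2L),
                           proportion = c(0.7, 0.2, 0.5, 0.3),
                           stringsAsFactors = FALSE),
    distances = data.frame(landscape_id = c("L1", "L2"),
                           dist_forest_m = c(100, 50),
                           dist_urban_m = c(10, 30), stringsAsFactors = FALSE),
    seedset = data.frame(landscape_id = rep(c("L1", "L2"), each = 3L),
                         pod_id = rep(paste0("pod", 1:3), 2L),
                         seeds = c(2L, 3L, 1L, 3L, 0L, 3L),
                         stringsAsFactors = FALSE)
  )
}

tiny_bundle <- function() do.call(as_bundle, tiny_tables())

# random rectangle with a class label, inside the [-r, r] square
random_rect_polygon <- function(r, class) {
  x <- sort(stats::runif(2, -r, r))
  y <- sort(stats::runif(2, -r, r))
  list(class = class,
       xy = cbind(c(x[1], x[2], x[2], x[1]), c(y[1], y[1], y[2], y[2])))
}

# area of the intersection of a polygon with the disc, by fine rasterization
raster_disc_areas <- function(polygons, center, radius, grid_n = 801L) {
  gx <- seq(center[1] - radius, center[1] + radius, length.out = grid_n)
  gy <- seq(center[2] - radius, center[2] + radius, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gy)
  keep <- (pts$x - center[1])^2 + (pts$y - center[2])^2 <= radius^2
  pts <- pts[keep, ]
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  vapply(polygons, function(p) {
    sum(floravail:::point_in_polygon(pts$x, pts$y, p$xy)) * cell
  }, numeric(1))
}

# independent brute-force all-subsets AICc oracle built on stats::lm/AIC
brute_force_selection <- function(y, X) {
  vars <- sort(colnames(X))
  subsets <- list(character(0))
  for (s in seq_along(vars)) {
    subsets <- c(subsets, utils::combn(vars, s, simplify = FALSE))
  }
  rows <- lapply(subsets, function(s) {
    dat <- data.frame(y = y, X)
    fml <- if (length(s) == 0L) y ~ 1 else
      stats::reformulate(s, response = "y")
    fit <- stats::lm(fml, data = dat)
    k <- attr(stats::logLik(fit), "df")
    n <- length(y)
    data.frame(model = if (length(s) == 0L) "(intercept only)" else
                 paste(s, collapse = " + "),
               size = length(s),
               aicc = stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc, tab$size, tab$model), ]
  tab$delta <- tab$aicc - tab$aicc[1L]
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab
}
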