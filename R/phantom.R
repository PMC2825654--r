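#' Axis-aligned box region
#'
#' @param lo,hi numeric 3-vectors, minimum and maximum corner in cm
#'   (`lo < hi` componentwise).
#' @param material an [material()] filling the box.
#' @return an object of class `box_region`.
#' @export
box_region <- function(lo, hi, material) {
  stopifnot(length(lo) == 3, length(hi) == 3,
            inherits(material, "xray_material"))
  if (!all(lo < hi)) stop("box corners must satisfy lo < hi componentwise")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 material = material),
            class = "box_region")
}

#' Box phantom: background slab plus axis-aligned box inclusions
#'
#' The geometry the simulator transports photons through: a background box
#' (e.g. a water slab) containing pairwise-disjoint box inclusions whose
#' materials override the background; everything outside the background is
#' vacuum. The beam travels along +z and enters at the background's low-z
#' face.
#'
#' @param background a [box_region()].
#' @param inclusions list of [box_region()]s, each fully inside the
#'   background and pairwise disjoint.
#' @return an object of class `xray_phantom`.
#' @export
phantom <- function(background, inclusions = list()) {
  stopifnot(inherits(background, "box_region"))
  for (inc in inclusions) {
    stopifnot(inherits(inc, "box_region"))
    if (!all(inc$lo >= background$lo) || !all(inc$hi <= background$hi))
      stop("inclusion '", inc$material$name,
           "' is not contained in the background")
  }
  n <- length(inclusions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- inclusions[[i]]; b <- inclusions[[j]]
      if (all(a$lo < b$hi) && all(b$lo < a$hi))
        stop("inclusions ", i, " and ", j, " overlap")
    }
  }
  structure(list(background = background, inclusions = inclusions),
            class = "xray_phantom")
}

#' @export
print.xray_phantom <- function(x, ...) {
  b <- x$background
  cat(sprintf("<phantom>  background '%s' [%g x %g x %g cm], %d inclusion(s)\n",
              b$material$name, diff(range(b$lo[1], b$hi[1])),
              b$hi[2] - b$lo[2], b$hi[3] - b$lo[3], length(x$inclusions)))
  for (inc in x$inclusions)
    cat(sprintf("  '%s' lo=(%g,%g,%g) hi=(%g,%g,%g)\n", inc$material$name,
                inc$lo[1], inc$lo[2], inc$lo[3],
                inc$hi[1], inc$hi[2], inc$hi[3]))
  invisible(x)
}

#' Reference phantom materials (water plus four test cubes)
#'
#' The five materials of the reference phantom at 50 keV: water
#' (`mu_t = 0.028`, `mu_s_r = 0.014`, `mu_s_c = 0.168`, all 1/cm) and four
#' cube materials sharing water's absorption and total scattering
#' coefficients but with Rayleigh/Compton splits ranging from a quarter of
#' water's Rayleigh coefficient to almost four times it. `beta` is carried
#' at full precision as `mu_s_r / (mu_s_r + mu_s_c)`.
#'
#' @return a named list of five [material()]s:
#'   `water`, `cube1`, `cube2`, `cube3`, `cube4`.
#' @export
table1_materials <- function() {
  comp <- data.frame(
    name  = c("water", "cube1", "cube2", "cube3", "cube4"),
    mu_t  = c(0.028, 0.028, 0.028, 0.028, 0.028),
    mu_sr = c(0.0140, 0.0035, 0.0070, 0.0260, 0.0520),
    mu_sc = c(0.1680, 0.1785, 0.1750, 0.1560, 0.1300))
  out <- lapply(seq_len(nrow(comp)), function(i)
    material_from_components(comp$name[i], comp$mu_t[i],
                             comp$mu_sr[i], comp$mu_sc[i]))
  names(out) <- comp$name
  out
}

#' Build the reference water-slab phantom with four test cubes
#'
#' A 10 x 10 x 5 cm^3 water slab spanning `[-5,5] x [-5,5] x [-2.5,2.5]` cm,
#' with four 1 cm^3 cubes of the [table1_materials()] cube materials centered
#' at mid-depth at the four lateral quadrant centers `(+-2.5, +-2.5, 0)` cm.
#' Cubes are indexed in reading order: cube1 at `(-2.5, +2.5)`, cube2 at
#' `(+2.5, +2.5)`, cube3 at `(-2.5, -2.5)`, cube4 at `(+2.5, -2.5)`.
#'
#' @param materials a named list as returned by [table1_materials()];
#'   override to change the cube materials.
#' @param cube_centers 4 x 2 matrix of lateral cube centers in cm.
#' @return an [phantom()].
#' @export
build_table1_phantom <- function(materials = table1_materials(),
                                 cube_centers = rbind(c(-2.5, 2.5),
                                                      c(2.5, 2.5),
                                                      c(-2.5, -2.5),
                                                      c(2.5, -2.5))) {
  stopifnot(nrow(cube_centers) == 4)
  bg <- box_region(c(-5, -5, -2.5), c(5, 5, 2.5), materials$water)
  cubes <- lapply(1:4, function(i) {
    cxy <- cube_centers[i, ]
    box_region(c(cxy[1] - 0.5, cxy[2] - 0.5, -0.5),
               c(cxy[1] + 0.5, cxy[2] + 0.5, 0.5),
               materials[[paste0("cube", i)]])
  })
  phantom(bg, cubes)
}

#' Material at a point
#'
#' Point lookup with inclusions overriding the background; points outside
#' the background return vacuum (`mu_t = mu_s = 0`).
#'
#' @param phantom an [phantom()].
#' @param point numeric 3-vector in cm.
#' @return an [material()].
#' @export
phantom_material_at <- function(phantom, point) {
  stopifnot(inherits(phantom, "xray_phantom"), length(point) == 3)
  inside <- function(b) all(point >= b$lo) && all(point <= b$hi)
  for (inc in phantom$inclusions) if (inside(inc)) return(inc$material)
  if (inside(phantom$background)) return(phantom$background$material)
  material("vacuum", 0, 0, 0)
}

# slab-method ray/box intersection; returns c(t0, t1) or NULL on miss
.ray_box <- function(origin, direction, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (i in 1:3) {
    if (direction[i] == 0) {
      if (origin[i] < lo[i] || origin[i] > hi[i]) return(NULL)
    } else {
      ta <- (lo[i] - origin[i]) / direction[i]
      tb <- (hi[i] - origin[i]) / direction[i]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  c(t0, t1)
}

#' Trace a ray through the phantom into material segments
#'
#' Partitions the ray's intersection with the phantom into segments of
#' constant material, with boundaries exactly at the box faces crossed.
#' Segment lengths sum to the chord length of the ray through the background
#' box (from the ray origin if it starts inside).
#'
#' @param phantom an [phantom()].
#' @param origin numeric 3-vector, ray origin in cm.
#' @param direction unit 3-vector.
#' @return a data.frame with columns `material` (name), `length` (cm),
#'   `t_enter`, `t_exit` (ray parameters); zero rows if the ray misses.
#' @export
trace_segments <- function(phantom, origin, direction) {
  stopifnot(inherits(phantom, "xray_phantom"),
            abs(sqrt(sum(direction^2)) - 1) < 1e-9)
  empty <- data.frame(material = character(), length = numeric(),
                      t_enter = numeric(), t_exit = numeric())
  bg <- phantom$background
  tt <- .ray_box(origin, direction, bg$lo, bg$hi)
  if (is.null(tt) || tt[2] <= 0) return(empty)
  t_in <- max(tt[1], 0); t_out <- tt[2]
  ts <- c(t_in, t_out)
  for (inc in phantom$inclusions) {
    ti <- .ray_box(origin, direction, inc$lo, inc$hi)
    if (!is.null(ti))
      ts <- c(ts, ti[ti > t_in & ti < t_out])
  }
  ts <- sort(unique(ts))
  mids <- (ts[-1] + ts[-length(ts)]) / 2
  mats <- vapply(mids, function(tm)
    phantom_material_at(phantom, origin + tm * direction)$name, "")
  data.frame(material = mats, length = diff(ts),
             t_enter = ts[-length(ts)], t_exit = ts[-1])
}

#' Sample a free-flight interaction point along a ray
#'
#' Draws an optical depth `-log(xi)` with `xi` uniform on (0, 1] and walks
#' the ray's material segments, accumulating `(mu_t + mu_s) * length`, until
#' the drawn depth is consumed; across region boundaries the step sizes
#' satisfy `sum_i (mu_t_i + mu_s_i) * s_i = -log(xi)`. If the total optical
#' depth along the remaining path is smaller, the photon escapes.
#'
#' @param phantom an [phantom()].
#' @param origin,direction ray origin (cm) and unit direction.
#' @param xi optional uniform (0,1] variate, drawn from R's RNG when `NULL`;
#'   pass explicitly for deterministic checks.
#' @return a list with `escaped` (logical); when `FALSE` also `position`
#'   (3-vector) and `material` ([material()] at the interaction point).
#' @export
sample_interaction <- function(phantom, origin, direction, xi = NULL) {
  if (is.null(xi)) xi <- max(1 - stats::runif(1), .Machine$double.xmin)
  stopifnot(xi > 0, xi <= 1)
  segs <- trace_segments(phantom, origin, direction)
  if (nrow(segs) == 0) return(list(escaped = TRUE))
  tau <- -log(xi)
  lut <- c(lapply(phantom$inclusions, `[[`, "material"),
           list(phantom$background$material))
  names(lut) <- vapply(lut, `[[`, "", "name")
  cum <- 0
  for (i in seq_len(nrow(segs))) {
    m <- lut[[segs$material[i]]]
    mu <- m$mu_t + m$mu_s
    seg <- mu * segs$length[i]
    if (cum + seg >= tau && mu > 0) {
      t_int <- segs$t_enter[i] + (tau - cum) / mu
      return(list(escaped = FALSE,
                  position = origin + t_int * direction,
                  material = m))
    }
    cum <- cum + seg
  }
  list(escaped = TRUE)
}

#' Write / read a phantom description file
#'
#' Plain-text YAML with the background box (corners + material) and a list
#' of inclusions; materials are stored inline as `(mu_t, mu_s, beta)`.
#' `read_phantom(write_phantom(p, f))` reproduces `p`.
#'
#' @param phantom an [phantom()].
#' @param path file path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` returns
#'   an [phantom()].
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "xray_phantom"))
  box2list <- function(b) list(
    lo = as.numeric(b$lo), hi = as.numeric(b$hi),
    material = list(name = b$material$name, mu_t = b$material$mu_t,
                    mu_s = b$material$mu_s, beta = b$material$beta))
  obj <- list(background = box2list(phantom$background),
              inclusions = lapply(phantom$inclusions, box2list))
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$background))
    stop("phantom config '", path, "': missing 'background'")
  list2box <- function(x) {
    m <- x$material
    for (f in c("name", "mu_t", "mu_s", "beta"))
      if (is.null(m[[f]])) stop("phantom config: material missing '", f, "'")
    box_region(unlist(x$lo), unlist(x$hi),
               material(m$name, m$mu_t, m$mu_s, m$beta))
  }
  phantom(list2box(obj$background), lapply(obj$inclusions, list2box))
}

#' Write / read a material table
#'
#' Tab-separated plain text with columns `name`, `mu_t`, then either
#' (`mu_s`, `beta`) or (`mu_s_r`, `mu_s_c`).
#'
#' @param materials named list of [material()]s.
#' @param path file path.
#' @return `write_material_table` returns `path` invisibly;
#'   `read_material_table` returns a named list of [material()]s.
#' @export
write_material_table <- function(materials, path) {
  df <- data.frame(
    name = vapply(materials, `[[`, "", "name"),
    mu_t = vapply(materials, `[[`, 0, "mu_t"),
    mu_s = vapply(materials, `[[`, 0, "mu_s"),
    beta = vapply(materials, `[[`, 0, "beta"))
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_table
#' @export
read_material_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "mu_t") %in% names(df)))
    stop("material table '", path, "': need columns 'name' and 'mu_t'")
  out <- if (all(c("mu_s", "beta") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i)
      material(df$name[i], df$mu_t[i], df$mu_s[i], df$beta[i]))
  } else if (all(c("mu_s_r", "mu_s_c") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i)
      material_from_components(df$name[i], df$mu_t[i],
                               df$mu_s_r[i], df$mu_s_c[i]))
  } else {
    stop("material table '", path,
         "': need columns ('mu_s','beta') or ('mu_s_r','mu_s_c')")
  }
  names(out) <- df$name
  out
}
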