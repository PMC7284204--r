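#' Topography design configuration
#'
#' Parameters of the generative grammar for feature blocks: the set of
#' primitive shapes, the size bounds (characteristic diameter in micrometers;
#' rectangle side lengths and triangle circumscribing diameters use the same
#' bounds), the number of primitives per block, the block edge length and the
#' common pillar height.
#'
#' Primitives are placed uniformly at random, fully inside the block
#' (position is rejected and resampled while the primitive's circumscribing
#' circle does not fit). Overlapping primitives are allowed; the rasterized
#' union defines the pillars.
#'
#' @param shapes character vector, subset of `c("circle", "triangle",
#'   "rectangle")`.
#' @param size_range numeric length 2, primitive size bounds in micrometers.
#'   The fabrication process this emulates supports 3-23 um; bounds outside
#'   that range are allowed but trigger a warning.
#' @param n_primitives_range integer length 2, inclusive range from which the
#'   number of primitives per block is drawn uniformly.
#' @param block_size feature-block edge length in micrometers.
#' @param height pillar height in micrometers (constant across a library).
#' @param max_attempts bounded-resampling budget for placement and library
#'   uniqueness.
#' @return a list of class `topo_config`.
#' @export
topo_config <- function(shapes = c("circle", "triangle", "rectangle"),
                        size_range = c(3, 23),
                        n_primitives_range = c(1L, 3L),
                        block_size = 29,
                        height = 10,
                        max_attempts = 100L) {
  shapes <- match.arg(shapes, c("circle", "triangle", "rectangle"),
                      several.ok = TRUE)
  stopifnot(length(size_range) == 2, size_range[1] > 0,
            size_range[1] <= size_range[2],
            length(n_primitives_range) == 2,
            n_primitives_range[1] >= 0,
            n_primitives_range[1] <= n_primitives_range[2],
            block_size > 0, height > 0, max_attempts >= 1)
  if (size_range[1] < 3 || size_range[2] > 23) {
    warning("size_range extends outside the standard fabrication bounds [3, 23] um",
            call. = FALSE)
  }
  structure(
    list(shapes = shapes,
         size_range = as.numeric(size_range),
         n_primitives_range = as.integer(n_primitives_range),
         block_size = as.numeric(block_size),
         height = as.numeric(height),
         max_attempts = as.integer(max_attempts)),
    class = "topo_config")
}

# circumscribing radius of a primitive (um); determines the placement margin
primitive_circumradius <- function(shape, size_a, size_b) {
  ifelse(shape == "rectangle",
         sqrt(size_a^2 + ifelse(is.na(size_b), size_a, size_b)^2) / 2,
         size_a / 2)
}

#' Draw one feature block from the generative grammar
#'
#' Consumes the current RNG stream (set a seed, or use [generate_library()]
#' which seeds for you). The number of primitives is drawn uniformly from
#' `config$n_primitives_range`, shapes uniformly from `config$shapes`, sizes
#' uniformly from `config$size_range`, rotations uniformly in [0, 360), and
#' positions uniformly such that the primitive lies fully inside the block.
#'
#' @param config a [topo_config()].
#' @param design_id identifier assigned to the design.
#' @return one-row tibble with columns `design_id`, `block_size`, `height`,
#'   `is_flat` and a `primitives` list-column (tibble with `shape`, `size_a`,
#'   `size_b`, `x`, `y`, `rotation`; sizes in um, positions um from the
#'   block's top-left corner).
#' @export
build_feature_block <- function(config = topo_config(), design_id = "D0001") {
  n <- if (config$n_primitives_range[1] == config$n_primitives_range[2]) {
    config$n_primitives_range[1]
  } else {
    sample(seq(config$n_primitives_range[1], config$n_primitives_range[2]), 1L)
  }
  if (n == 0L) {
    prim <- tibble::tibble(shape = character(), size_a = numeric(),
                           size_b = numeric(), x = numeric(), y = numeric(),
                           rotation = numeric())
    return(tibble::tibble(design_id = design_id,
                          block_size = config$block_size,
                          height = config$height, is_flat = TRUE,
                          primitives = list(prim)))
  }
  shp <- character(n); sa <- sb <- px <- py <- rot <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      shape <- sample(config$shapes, 1L)
      size_a <- runif(1, config$size_range[1], config$size_range[2])
      size_b <- if (shape == "rectangle") {
        runif(1, config$size_range[1], config$size_range[2])
      } else NA_real_
      cr <- primitive_circumradius(shape, size_a, size_b)
      if (2 * cr > config$block_size) next   # cannot fit; resample size/shape
      shp[i] <- shape; sa[i] <- size_a; sb[i] <- size_b
      px[i] <- runif(1, cr, config$block_size - cr)
      py[i] <- runif(1, cr, config$block_size - cr)
      rot[i] <- runif(1, 0, 360)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place a primitive inside the block after ",
           config$max_attempts, " attempts; enlarge block_size or shrink size_range",
           call. = FALSE)
    }
  }
  tibble::tibble(design_id = design_id, block_size = config$block_size,
                 height = config$height, is_flat = FALSE,
                 primitives = list(tibble::tibble(shape = shp, size_a = sa,
                                                  size_b = sb, x = px, y = py,
                                                  rotation = rot)))
}

# canonical key for uniqueness checks: order-independent, coordinate-rounded
design_key <- function(primitives) {
  if (nrow(primitives) == 0) return("flat")
  s <- sprintf("%s|%.6f|%.6f|%.6f|%.6f|%.6f",
               primitives$shape, primitives$size_a,
               ifelse(is.na(primitives$size_b), -1, primitives$size_b),
               primitives$x, primitives$y, primitives$rotation)
  paste(sort(s), collapse = ";")
}

#' Generate a topography design library
#'
#' Draws `n_designs` unique feature blocks (canonical comparison of their
#' primitive sets). Regenerating with the same seed and configuration yields
#' an identical library.
#'
#' @param n_designs number of unique designs (the standard chip carries 2176).
#' @param seed integer RNG seed.
#' @param config a [topo_config()].
#' @return tibble of class `topo_library`, one row per design (see
#'   [build_feature_block()]), with the configuration and seed as attributes.
#' @export
generate_library <- function(n_designs = 2176, seed = 1, config = topo_config()) {
  stopifnot(n_designs >= 1)
  withr::with_seed(as.integer(seed), {
    designs <- vector("list", n_designs)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    i <- 1L
    tries <- 0L
    max_tries <- n_designs * config$max_attempts
    flat <- logical(n_designs)
    while (i <= n_designs) {
      d <- build_feature_block(config, design_id = sprintf("D%05d", i))
      k <- design_key(d$primitives[[1]])
      tries <- tries + 1L
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        designs[[i]] <- d$primitives[[1]]
        flat[i] <- d$is_flat
        i <- i + 1L
      } else if (tries > max_tries) {
        stop("design space too small to draw ", n_designs, " unique designs",
             call. = FALSE)
      }
    }
    lib <- tibble::tibble(design_id = sprintf("D%05d", seq_len(n_designs)),
                          block_size = config$block_size,
                          height = config$height,
                          is_flat = flat,
                          primitives = designs)
    attr(lib, "config") <- config
    attr(lib, "seed") <- as.integer(seed)
    class(lib) <- c("topo_library", class(lib))
    lib
  })
}

#' Lay out a design library on a chip grid
#'
#' Every design is placed twice; the duplicate sits at the diagonal offset
#' `(row + g/2, col + g/2) mod g` for a grid of edge `g` (33 units for the
#' standard 66 x 66 chip), so the offset map pairs the grid into orbits of
#' size two. Flat control units occupy `n_flats` slots (orbit pairs), by
#' default the corners of one quadrant diagonal.
#'
#' @param library a `topo_library`.
#' @param grid_dim grid edge length in units (default 66).
#' @param n_flats number of flat control slots (must be even; default 4).
#' @return tibble of class `topo_layout` with columns `row`, `col` (1-based),
#'   `design_id` (`"FLAT"` for controls) and `is_flat`; attributes
#'   `duplicate_offset` and `grid_dim`.
#' @export
layout_chip <- function(library, grid_dim = 66, n_flats = 4) {
  n <- nrow(library)
  if (2 * n + n_flats != grid_dim^2) {
    stop("library size incompatible with grid: need 2*", n, " + ", n_flats,
         " = ", grid_dim^2, " slots", call. = FALSE)
  }
  if (n_flats %% 2 != 0) stop("n_flats must be even (flats are duplicated too)")
  off <- grid_dim / 2
  if (off != round(off)) stop("grid_dim must be even for the diagonal duplicate rule")
  # orbit representatives: 0-based slots (r, c) with r < off (each orbit has
  # exactly one member in the top half of the grid)
  reps <- expand.grid(r = 0:(off - 1), c = 0:(grid_dim - 1))
  reps <- reps[order(reps$r, reps$c), ]
  # flat controls: orbits whose slots sit at the quadrant corners first
  flat_cols <- unique(c(0, off, setdiff(0:(grid_dim - 1), c(0, off))))
  flat_reps <- data.frame(r = 0, c = head(flat_cols, n_flats / 2))
  is_flat_rep <- paste(reps$r, reps$c) %in% paste(flat_reps$r, flat_reps$c)
  design_reps <- reps[!is_flat_rep, , drop = FALSE]
  r1 <- c(flat_reps$r, design_reps$r)
  c1 <- c(flat_reps$c, design_reps$c)
  ids <- c(rep("FLAT", nrow(flat_reps)), library$design_id)
  fl <- c(rep(TRUE, nrow(flat_reps)), rep(FALSE, n))
  layout <- tibble::tibble(row = c(r1, (r1 + off) %% grid_dim) + 1,
                           col = c(c1, (c1 + off) %% grid_dim) + 1,
                           design_id = c(ids, ids), is_flat = c(fl, fl))
  layout <- dplyr::arrange(layout, .data$row, .data$col)
  attr(layout, "duplicate_offset") <- c(off, off)
  attr(layout, "grid_dim") <- grid_dim
  class(layout) <- c("topo_layout", class(layout))
  layout
}

#' Write / read a design library as JSON
#'
#' One record per design: id, block size, height, and the primitive list.
#'
#' @param library a `topo_library`.
#' @param path file path.
#' @return `write_library` returns `path` invisibly; `read_library` a
#'   `topo_library` tibble.
#' @export
write_library <- function(library, path) {
  recs <- purrr::map(seq_len(nrow(library)), function(i) {
    list(design_id = library$design_id[i],
         block_size = library$block_size[i],
         height = library$height[i],
         is_flat = library$is_flat[i],
         primitives = library$primitives[[i]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- tibble::tibble(
    design_id = purrr::map_chr(recs, "design_id"),
    block_size = purrr::map_dbl(recs, "block_size"),
    height = purrr::map_dbl(recs, "height"),
    is_flat = purrr::map_lgl(recs, "is_flat"),
    primitives = purrr::map(recs, function(r) {
      p <- r$primitives
      if (is.null(p) || length(p) == 0) {
        tibble::tibble(shape = character(), size_a = numeric(),
                       size_b = numeric(), x = numeric(), y = numeric(),
                       rotation = numeric())
      } else {
        dplyr::bind_rows(purrr::map(p, function(q) {
          tibble::tibble(shape = q$shape, size_a = q$size_a,
                         size_b = if (is.null(q$size_b)) NA_real_ else q$size_b,
                         x = q$x, y = q$y, rotation = q$rotation)
        }))
      }
    }))
  class(lib) <- c("topo_library", class(lib))
  lib
}
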