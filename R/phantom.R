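# Voxelized phantoms: boolean solid geometry, slab/film depth-dose stacks,
# lead slit shields, and MetaImage-style I/O.
#
# Coordinate convention: right-handed world frame with the origin
# ("isocenter") at the centre of the shelf top surface; +z points from the
# shelf toward the x-ray source, the beam travels along -z. Voxels cover the
# half-open interval [corner, corner + size). The x-y grid is uniform; the z
# grid is a list of plane edges and may be non-uniform so thin films and
# shields are represented exactly.

#' Construct a voxel phantom
#'
#' @param labels 3D integer array (nx, ny, nz) of 1-based indices into
#'   \code{materials}.
#' @param origin World coordinates (mm) of the corner of voxel (1,1,1).
#' @param dx,dy Uniform lateral voxel size in mm.
#' @param z_edges Vector of nz + 1 ascending z plane positions in mm.
#' @param materials List of materials (names or \code{kv_material}) indexed
#'   by the label values.
#' @return An object of class \code{kv_phantom}.
#' @export
voxel_phantom <- function(labels, origin, dx, dy, z_edges, materials) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (dx <= 0 || dy <= 0) stop("voxel sizes must be positive")
  if (any(diff(z_edges) <= 0)) stop("z_edges must be strictly ascending")
  if (length(z_edges) != dim(labels)[3] + 1L) {
    stop("z_edges must have one more entry than the z dimension")
  }
  if (prod(dim(labels)) == 0) stop("phantom grid is empty")
  materials <- lapply(materials, get_material)
  if (any(labels < 1L) || any(labels > length(materials))) {
    stop("labels reference materials missing from the material table")
  }
  structure(list(labels = labels, origin = as.numeric(origin),
                 dx = dx, dy = dy, z_edges = as.numeric(z_edges),
                 materials = materials),
            class = "kv_phantom")
}

#' @export
print.kv_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom> %d x %d x %d voxels, %.3g x %.3g mm lateral, z [%.2f, %.2f] mm\n",
              d[1], d[2], d[3], x$dx, x$dy, min(x$z_edges), max(x$z_edges)))
  counts <- table(x$labels)
  for (i in names(counts)) {
    cat(sprintf("  %-18s %d voxels\n",
                x$materials[[as.integer(i)]]$name, counts[[i]]))
  }
  invisible(x)
}

# voxel center coordinates along each axis
phantom_centers <- function(ph) {
  d <- dim(ph$labels)
  list(x = ph$origin[1] + (seq_len(d[1]) - 0.5) * ph$dx,
       y = ph$origin[2] + (seq_len(d[2]) - 0.5) * ph$dy,
       z = (ph$z_edges[-1] + ph$z_edges[-length(ph$z_edges)]) / 2)
}

# ---- boolean solid shapes --------------------------------------------------

#' Geometric shape primitives and boolean combinations
#'
#' Shapes are defined in world coordinates (mm) and combined with boolean
#' operators; voxel membership is decided by a voxel-center-inside test in
#' \code{\link{voxelize}}.
#'
#' @param center Shape center (x, y, z) in mm.
#' @param size Box edge lengths (mm).
#' @return A \code{kv_shape} object.
#' @export
shape_box <- function(center, size) {
  if (any(size <= 0)) stop("box dimensions must be positive")
  structure(list(type = "box", center = center, size = size),
            class = "kv_shape")
}

#' @rdname shape_box
#' @param radius Cylinder radius (mm).
#' @param height Cylinder height (mm).
#' @param axis Cylinder axis: "x", "y" or "z".
#' @export
shape_cylinder <- function(center, radius, height, axis = "z") {
  if (radius <= 0 || height <= 0) stop("cylinder dimensions must be positive")
  structure(list(type = "cylinder", center = center, radius = radius,
                 height = height, axis = match.arg(axis, c("x", "y", "z"))),
            class = "kv_shape")
}

#' @rdname shape_box
#' @param semiaxes Ellipsoid semi-axis lengths (mm).
#' @export
shape_ellipsoid <- function(center, semiaxes) {
  if (any(semiaxes <= 0)) stop("ellipsoid semi-axes must be positive")
  structure(list(type = "ellipsoid", center = center, semiaxes = semiaxes),
            class = "kv_shape")
}

#' @rdname shape_box
#' @param a,b Shapes to combine.
#' @export
shape_union <- function(a, b) {
  structure(list(type = "union", a = a, b = b), class = "kv_shape")
}

#' @rdname shape_box
#' @export
shape_intersection <- function(a, b) {
  structure(list(type = "intersection", a = a, b = b), class = "kv_shape")
}

#' @rdname shape_box
#' @export
shape_difference <- function(a, b) {
  structure(list(type = "difference", a = a, b = b), class = "kv_shape")
}

#' Test points against a shape
#' @param shape A \code{kv_shape}.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Logical vector of length n.
#' @export
shape_inside <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  switch(shape$type,
    box = {
      h <- shape$size / 2
      abs(pts[, 1] - shape$center[1]) <= h[1] &
        abs(pts[, 2] - shape$center[2]) <= h[2] &
        abs(pts[, 3] - shape$center[3]) <= h[3]
    },
    cylinder = {
      ax <- match(shape$axis, c("x", "y", "z"))
      others <- setdiff(1:3, ax)
      r2 <- (pts[, others[1]] - shape$center[others[1]])^2 +
        (pts[, others[2]] - shape$center[others[2]])^2
      r2 <= shape$radius^2 &
        abs(pts[, ax] - shape$center[ax]) <= shape$height / 2
    },
    ellipsoid = {
      s <- sweep(sweep(pts, 2, shape$center), 2, shape$semiaxes, "/")
      rowSums(s^2) <= 1
    },
    union = shape_inside(shape$a, pts) | shape_inside(shape$b, pts),
    intersection = shape_inside(shape$a, pts) & shape_inside(shape$b, pts),
    difference = shape_inside(shape$a, pts) & !shape_inside(shape$b, pts),
    stop("unknown shape type ", shape$type)
  )
}

#' Voxelize a list of shapes
#'
#' Later shapes overwrite earlier ones; voxel membership is decided by a
#' voxel-center-inside test (no volume-fraction antialiasing).
#'
#' @param shapes List of \code{list(shape = , material = )} entries, in
#'   painting order.
#' @param bounds List with x, y, z two-element ranges (mm).
#' @param voxel_size Voxel edge lengths (dx, dy, dz) in mm (scalar recycled).
#' @param background Background material (default air).
#' @return A \code{kv_phantom}.
#' @export
voxelize <- function(shapes, bounds, voxel_size, background = "air") {
  voxel_size <- rep(voxel_size, length.out = 3)
  ext <- c(diff(bounds$x), diff(bounds$y), diff(bounds$z))
  if (any(voxel_size > ext)) stop("voxel_size larger than bounds")
  n <- pmax(1L, as.integer(round(ext / voxel_size)))
  origin <- c(bounds$x[1], bounds$y[1], bounds$z[1])
  xc <- origin[1] + (seq_len(n[1]) - 0.5) * voxel_size[1]
  yc <- origin[2] + (seq_len(n[2]) - 0.5) * voxel_size[2]
  zc <- origin[3] + (seq_len(n[3]) - 0.5) * voxel_size[3]
  pts <- as.matrix(expand.grid(x = xc, y = yc, z = zc))
  materials <- list(get_material(background))
  labels <- array(1L, dim = n)
  for (entry in shapes) {
    mat <- get_material(entry$material)
    idx <- which(vapply(materials, function(m) identical(m, mat), TRUE))
    if (!length(idx)) {
      materials <- c(materials, list(mat))
      idx <- length(materials)
    }
    labels[shape_inside(entry$shape, pts)] <- as.integer(idx[1])
  }
  voxel_phantom(labels, origin, voxel_size[1], voxel_size[2],
                z_edges = origin[3] + (0:n[3]) * voxel_size[3],
                materials = materials)
}

# check that a length is an integer multiple of the voxel pitch
.check_on_grid <- function(len, pitch, what) {
  if (abs(len / pitch - round(len / pitch)) > 1e-6) {
    stop(what, " (", len, " mm) is not representable on the ", pitch,
         " mm lateral grid; choose a compatible voxel size")
  }
}

#' Build the slab/film depth-dose phantom
#'
#' A stack of square slabs interleaved with n_slabs + 1 thin film layers
#' (film, slab, film, ..., slab, film from the top), on a base slab,
#' optionally on the PMMA shelf. The z grid resolves every film exactly.
#' Defaults reproduce the Plastic Water LR depth-dose stack: four
#' 60 mm x 60 mm slabs of 5.04 mm, five 0.278 mm films, a 10 mm base and the
#' 10 mm shelf (total stack height 4 x 5.04 + 5 x 0.278 + 10 = 31.55 mm).
#'
#' @param slab_material Slab material (default Plastic Water LR; use
#'   \code{"rb2_bone"} with \code{slab_thickness = 5.03} for the bone stack).
#' @param n_slabs Number of slabs (>= 1).
#' @param slab_thickness Slab thickness in mm.
#' @param film_thickness Film layer thickness in mm; 0 omits films.
#' @param base_thickness Base slab thickness in mm.
#' @param shelf Include the 10 mm PMMA shelf below the base.
#' @param film_material Film layer material: water by default (films are
#'   calibrated to report dose to water); \code{"plastic_water_lr"} is the
#'   documented alternative.
#' @param lateral_mm Slab edge length in mm (square).
#' @param voxel_xy_mm Lateral voxel size in mm.
#' @param margin_mm Air margin beyond the slab footprint on each side
#'   (the shelf spans the whole cropped grid).
#' @param slab_subdivision Number of z cells per slab.
#' @return A \code{kv_phantom} with attributes \code{film_z_mm} (film center
#'   z coordinates) and \code{film_depth_mm} (film center depths below the
#'   stack top surface).
#' @export
build_depth_dose_phantom <- function(slab_material = "plastic_water_lr",
                                     n_slabs = 4, slab_thickness = 5.04,
                                     film_thickness = 0.278,
                                     base_thickness = 10, shelf = TRUE,
                                     film_material = "water",
                                     lateral_mm = 60, voxel_xy_mm = 1,
                                     margin_mm = 20, slab_subdivision = 2) {
  if (n_slabs < 1) stop("n_slabs must be >= 1")
  .check_on_grid(lateral_mm, voxel_xy_mm, "slab edge")
  .check_on_grid(margin_mm, voxel_xy_mm, "margin")

  mats <- list(air = get_material("air"),
               slab = get_material(slab_material),
               film = if (film_thickness > 0) get_material(film_material),
               base = get_material("plastic_water_lr"),
               shelf = if (shelf) get_material("pmma"))

  # z structure from the shelf upward
  z <- if (shelf) seq(-10, 0, length.out = 3) else 0
  kinds <- if (shelf) c("shelf", "shelf") else character()
  add_layer <- function(z, kinds, thickness, kind, cells = 1L) {
    list(z = c(z, utils::tail(z, 1) + seq_len(cells) / cells * thickness),
         kinds = c(kinds, rep(kind, cells)))
  }
  st <- add_layer(z, kinds, base_thickness, "base", 2L)
  film_z <- numeric()
  for (i in seq_len(n_slabs)) {
    if (film_thickness > 0) {
      film_z <- c(film_z, utils::tail(st$z, 1) + film_thickness / 2)
      st <- add_layer(st$z, st$kinds, film_thickness, "film")
    }
    st <- add_layer(st$z, st$kinds, slab_thickness, "slab",
                    as.integer(slab_subdivision))
  }
  if (film_thickness > 0) {
    film_z <- c(film_z, utils::tail(st$z, 1) + film_thickness / 2)
    st <- add_layer(st$z, st$kinds, film_thickness, "film")
  }

  half_ext <- lateral_mm / 2 + margin_mm
  n_xy <- as.integer(round(2 * half_ext / voxel_xy_mm))
  nz <- length(st$kinds)
  labels <- array(1L, dim = c(n_xy, n_xy, nz))

  used <- list(mats$air)
  lab_of <- function(m) {
    for (i in seq_along(used)) if (identical(used[[i]], m)) return(i)
    used[[length(used) + 1L]] <<- m
    length(used)
  }
  xc <- -half_ext + (seq_len(n_xy) - 0.5) * voxel_xy_mm
  inside <- abs(xc) <= lateral_mm / 2
  foot <- outer(inside, inside, "&")
  for (k in seq_len(nz)) {
    kind <- st$kinds[k]
    m <- mats[[kind]]
    if (kind == "shelf") {
      labels[, , k] <- lab_of(m)        # shelf spans the cropped grid
    } else {
      sl <- labels[, , k]
      sl[foot] <- lab_of(m)
      labels[, , k] <- sl
    }
  }
  ph <- voxel_phantom(labels, origin = c(-half_ext, -half_ext, st$z[1]),
                      dx = voxel_xy_mm, dy = voxel_xy_mm,
                      z_edges = st$z, materials = used)
  top <- utils::tail(st$z, 1)
  attr(ph, "film_z_mm") <- film_z
  attr(ph, "film_depth_mm") <- top - film_z
  attr(ph, "top_z_mm") <- top
  ph
}

#' Add a slit shield on top of a phantom
#'
#' Places a shield layer (default 80 x 80 x 3.454 mm lead) directly on the
#' phantom's top surface, with a full-length central slit running along y.
#' The whole assembly can be translated laterally (a 100 mm
#' offset puts the slit center at world x = -offset).
#'
#' @param phantom A \code{kv_phantom}.
#' @param slit_width_mm Slit width in mm (must be smaller than the shield
#'   width and representable on the lateral grid).
#' @param shield_size_mm Shield (width, length) in mm.
#' @param thickness_mm Shield thickness in mm.
#' @param mat Shield material (default lead).
#' @param lateral_offset_mm Lateral offset of the whole assembly in mm.
#' @param n_layers Number of z cells across the shield thickness.
#' @return The augmented \code{kv_phantom}.
#' @export
add_slit_shield <- function(phantom, slit_width_mm,
                            shield_size_mm = c(80, 80), thickness_mm = 3.454,
                            mat = "lead", lateral_offset_mm = 0,
                            n_layers = 2L) {
  if (slit_width_mm >= shield_size_mm[1]) {
    stop("slit width must be smaller than the shield width")
  }
  .check_on_grid(slit_width_mm, phantom$dx, "slit width")
  .check_on_grid(shield_size_mm[1], phantom$dx, "shield width")
  .check_on_grid(shield_size_mm[2], phantom$dy, "shield length")
  mat <- get_material(mat)
  materials <- phantom$materials
  idx <- which(vapply(materials, function(m) identical(m, mat), TRUE))
  if (!length(idx)) {
    materials <- c(materials, list(mat))
    idx <- length(materials)
  }

  d <- dim(phantom$labels)
  ctr <- phantom_centers(phantom)
  in_shield_x <- abs(ctr$x) <= shield_size_mm[1] / 2 &
    abs(ctr$x) >= slit_width_mm / 2
  in_shield_y <- abs(ctr$y) <= shield_size_mm[2] / 2
  layer <- array(1L, dim = c(d[1], d[2]))
  layer[outer(in_shield_x, in_shield_y, "&")] <- as.integer(idx[1])

  top <- utils::tail(phantom$z_edges, 1)
  new_edges <- c(phantom$z_edges,
                 top + seq_len(n_layers) / n_layers * thickness_mm)
  labels <- array(1L, dim = c(d[1], d[2], d[3] + n_layers))
  labels[, , seq_len(d[3])] <- phantom$labels
  for (k in seq_len(n_layers)) labels[, , d[3] + k] <- layer

  out <- voxel_phantom(labels,
                       origin = phantom$origin - c(lateral_offset_mm, 0, 0),
                       dx = phantom$dx, dy = phantom$dy,
                       z_edges = new_edges, materials = materials)
  for (a in c("film_z_mm", "film_depth_mm", "top_z_mm")) {
    attr(out, a) <- attr(phantom, a)
  }
  attr(out, "slit_width_mm") <- slit_width_mm
  out
}

# ---- MetaImage-style I/O ---------------------------------------------------

#' Write / read a voxel phantom
#'
#' Writes a MetaImage header/raw pair (\code{<base>.mhd} / \code{<base>.raw},
#' MET_SHORT labels, little-endian) plus a YAML sidecar
#' (\code{<base>_materials.yaml}) holding the exact z plane edges and the
#' material table. \code{read_phantom} reproduces labels and geometry
#' exactly.
#'
#' @param phantom A \code{kv_phantom}.
#' @param base Path base (without extension).
#' @return \code{write_phantom}: base path invisibly; \code{read_phantom}:
#'   a \code{kv_phantom}.
#' @export
write_phantom <- function(phantom, base) {
  d <- dim(phantom$labels)
  dz <- diff(phantom$z_edges)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g",
                   phantom$dx, phantom$dy, mean(dz)),
           sprintf("Offset = %.9g %.9g %.9g", phantom$origin[1],
                   phantom$origin[2], phantom$origin[3]),
           "ElementType = MET_SHORT",
           sprintf("ElementDataFile = %s.raw", basename(base)))
  writeLines(hdr, paste0(base, ".mhd"))
  con <- file(paste0(base, ".raw"), "wb")
  writeBin(as.integer(phantom$labels), con, size = 2L, endian = "little")
  close(con)
  side <- list(
    schema_version = 1,
    z_edges = phantom$z_edges,
    materials = lapply(phantom$materials, function(m) {
      list(name = m$name, density = m$density,
           composition = as.list(m$composition), note = m$note)
    })
  )
  yaml::write_yaml(side, paste0(base, "_materials.yaml"))
  invisible(base)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(base) {
  hdr <- readLines(paste0(base, ".mhd"))
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  con <- file(paste0(base, ".raw"), "rb")
  raw_labels <- readBin(con, "integer", n = prod(d), size = 2L,
                        endian = "little")
  close(con)
  side <- yaml::read_yaml(paste0(base, "_materials.yaml"))
  materials <- lapply(side$materials, function(m) {
    material(m$name, m$density, unlist(m$composition), note = m$note)
  })
  voxel_phantom(array(raw_labels, dim = d), origin = off,
                dx = sp[1], dy = sp[2],
                z_edges = as.numeric(side$z_edges), materials = materials)
}
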