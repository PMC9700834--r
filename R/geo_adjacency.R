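#' Read areal-unit polygons from a GeoJSON FeatureCollection
#'
#' Each feature becomes one zone. `Polygon` geometries contribute their rings;
#' `MultiPolygon` geometries keep every ring of every part under the same zone
#' id, so archipelago zones stay a single areal unit.
#'
#' @param path Path to a GeoJSON file (WGS84 lon/lat).
#' @param id_prop Name of the feature property holding the zone identifier.
#' @param name_prop Optional property with a display label.
#' @return A list of zone geometries, each a list with elements `zone_id`
#'   (character), `rings` (list of two-column lon/lat matrices, closed) and
#'   `area_name` (character or `NA`). Input feature order is preserved.
#' @export
read_geojson <- function(path, id_prop = "zone_id", name_prop = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || !identical(gj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  zones <- lapply(seq_along(gj$features), function(fi) {
    ft <- gj$features[[fi]]
    id <- ft$properties[[id_prop]]
    if (is.null(id) || !nzchar(as.character(id))) {
      stop("feature ", fi, " is missing id property '", id_prop, "'")
    }
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, ring_to_matrix)
      }), recursive = FALSE),
      stop("feature '", id, "': unsupported geometry type ", geom$type)
    )
    nm <- if (!is.null(name_prop)) ft$properties[[name_prop]] else NULL
    new_zone(as.character(id), rings, if (is.null(nm)) NA_character_ else nm)
  })
  ids <- vapply(zones, `[[`, character(1), "zone_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate zone id(s) in ", path, ": ", paste(dup, collapse = ", "))
  zones
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  storage.mode(m) <- "double"
  colnames(m) <- c("lon", "lat")
  m
}

new_zone <- function(zone_id, rings, area_name = NA_character_) {
  for (r in rings) {
    if (nrow(unique(r)) < 3) stop("zone '", zone_id, "': ring with < 3 distinct vertices")
  }
  # close rings
  rings <- lapply(rings, function(r) {
    if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE))) r <- rbind(r, r[1, ])
    r
  })
  list(zone_id = zone_id, rings = rings, area_name = area_name)
}

#' Write zone geometries as a GeoJSON FeatureCollection
#'
#' @param zones List of zone geometries as returned by [read_geojson()] or
#'   [make_grid_geometry()].
#' @param path Output file.
#' @param id_prop Property name used for the zone id.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(zones, path, id_prop = "zone_id") {
  features <- lapply(zones, function(z) {
    coords <- lapply(z$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    props <- stats::setNames(list(z$zone_id), id_prop)
    if (!is.na(z$area_name)) props$area_name <- z$area_name
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Squared distance from point p to segment (a, b); planar lon/lat.
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- ifelse(L2 == 0, 0,
              pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / pmax(L2, .Machine$double.xmin))))
  qx <- ax + t * dx; qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

boundary_points <- function(z) do.call(rbind, z$rings)

# Minimum distance between the boundaries of two zones, as the smallest
# vertex-to-segment distance taken in both directions. Touching polygons in a
# tessellation always realise their contact at such a pair.
min_boundary_dist <- function(za, zb) {
  d2 <- Inf
  for (ra in za$rings) for (rb in zb$rings) {
    na <- nrow(ra); nb <- nrow(rb)
    for (i in seq_len(na)) {
      j <- seq_len(nb - 1)
      d2 <- min(d2, min(point_seg_dist2(ra[i, 1], ra[i, 2],
                                        rb[j, 1], rb[j, 2], rb[j + 1, 1], rb[j + 1, 2])))
    }
    for (i in seq_len(nb)) {
      j <- seq_len(na - 1)
      d2 <- min(d2, min(point_seg_dist2(rb[i, 1], rb[i, 2],
                                        ra[j, 1], ra[j, 2], ra[j + 1, 1], ra[j + 1, 2])))
    }
  }
  sqrt(d2)
}

ring_area <- function(r) {
  n <- nrow(r)
  abs(sum(r[-n, 1] * r[-1, 2] - r[-1, 1] * r[-n, 2])) / 2
}

#' Queen-contiguity adjacency matrix from polygon geometries
#'
#' Two zones are neighbours when their boundaries share at least one point
#' (edge or corner contact), tested as minimum boundary distance `<= tol`.
#'
#' @param zones List of zone geometries.
#' @param tol Contact tolerance in degrees (default 0: exact touch).
#' @return An object of class `queen_adjacency`: list with `zone_ids`, binary
#'   symmetric matrix `W` (zero diagonal), neighbour index lists `nb`,
#'   `islands` (zone ids with no neighbours) and `n_components`.
#' @export
queen_adjacency <- function(zones, tol = 0) {
  stopifnot(length(zones) >= 1, tol >= 0)
  ids <- vapply(zones, `[[`, character(1), "zone_id")
  n <- length(zones)
  for (z in zones) {
    if (sum(vapply(z$rings, ring_area, numeric(1))) == 0) {
      warning("zone '", z$zone_id, "' has zero area; processed anyway")
    }
  }
  bbox <- t(vapply(zones, function(z) {
    pts <- boundary_points(z)
    c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2]))
  }, numeric(4)))
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (bbox[i, 1] > bbox[j, 2] + tol || bbox[j, 1] > bbox[i, 2] + tol ||
          bbox[i, 3] > bbox[j, 4] + tol || bbox[j, 3] > bbox[i, 4] + tol) next
      if (min_boundary_dist(zones[[i]], zones[[j]]) <= tol) W[i, j] <- W[j, i] <- 1L
    }
  }
  adjacency_from_matrix(W, ids)
}

adjacency_from_matrix <- function(W, ids = rownames(W)) {
  nb <- lapply(seq_len(nrow(W)), function(i) which(W[i, ] == 1L))
  islands <- ids[rowSums(W) == 0]
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", diag = FALSE)
  structure(list(zone_ids = ids, W = W, nb = nb, islands = islands,
                 n_components = igraph::components(g)$no),
            class = "queen_adjacency")
}

#' Validate an adjacency matrix
#'
#' Checks symmetry, a zero diagonal and 0/1 entries; on failure lists the
#' offending entries.
#'
#' @param A A `queen_adjacency` object or a plain square matrix.
#' @return List with `ok`, `failures` (character), row sums `m` and
#'   `n_components`.
#' @export
validate_adjacency <- function(A) {
  W <- if (inherits(A, "queen_adjacency")) A$W else as.matrix(A)
  failures <- character(0)
  bad <- which(W != t(W), arr.ind = TRUE)
  if (nrow(bad)) {
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    failures <- c(failures, sprintf("asymmetry at (%d,%d)", bad[, 1], bad[, 2]))
  }
  dg <- which(diag(W) != 0)
  if (length(dg)) failures <- c(failures, sprintf("nonzero diagonal at (%d,%d)", dg, dg))
  nb01 <- which(!(W %in% c(0, 1)))
  if (length(nb01)) failures <- c(failures, sprintf("non-binary entry at index %d", nb01))
  g <- igraph::graph_from_adjacency_matrix((W != 0) * 1L, mode = "max", diag = FALSE)
  list(ok = length(failures) == 0, failures = failures,
       m = rowSums(W), n_components = igraph::components(g)$no)
}

#' Export adjacency as neighbour-list and dense CSV files
#'
#' Writes `<prefix>_nb.txt` (one line per zone: id, neighbour count, neighbour
#' ids) and `<prefix>_W.csv` (dense 0/1 matrix with zone-id header).
#'
#' @param A A `queen_adjacency` object.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_adjacency <- function(A, prefix) {
  nb_path <- paste0(prefix, "_nb.txt")
  lines <- vapply(seq_along(A$zone_ids), function(i) {
    paste(c(A$zone_ids[i], length(A$nb[[i]]), A$zone_ids[A$nb[[i]]]), collapse = " ")
  }, character(1))
  writeLines(lines, nb_path)
  w_path <- paste0(prefix, "_W.csv")
  utils::write.csv(as.data.frame(A$W), w_path, row.names = TRUE)
  invisible(c(nb_path, w_path))
}
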