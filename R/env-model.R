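# Spatial environment: nested shopping zones, road network, OD distances.
# Coordinates are planar and in miles throughout; no geodesy.

# ---- zones ------------------------------------------------------------------

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Nested shopping-zone partition
#'
#' Two nested polygons partition the plane into three zones: points in the
#' neighborhood polygon, points in the city polygon only, and the suburbs
#' (everything else). The neighborhood must be strictly contained in the city.
#'
#' @param neighborhood,city two-column matrices of polygon vertices (miles).
#' @return an object of class `zone_partition`.
#' @export
zone_partition <- function(neighborhood, city) {
  nb <- close_ring(neighborhood); ci <- close_ring(city)
  if (nrow(nb) < 4 || nrow(ci) < 4)
    stop_fmt("partition error: polygons need at least 3 vertices")
  # strict nesting: every neighborhood vertex interior to the city polygon
  inside <- mgcv::in.out(ci, nb[-nrow(nb), , drop = FALSE])
  on_edge <- point_on_ring(nb[-nrow(nb), 1], nb[-nrow(nb), 2], ci)
  if (!all(inside) || any(on_edge))
    stop_fmt("partition error: neighborhood polygon is not strictly contained in the city polygon")
  structure(list(neighborhood = nb, city = ci), class = "zone_partition")
}

# TRUE where point i lies on the boundary of `ring` (within eps)
point_on_ring <- function(x, y, ring, eps = 1e-9) {
  out <- logical(length(x))
  for (s in seq_len(nrow(ring) - 1)) {
    ax <- ring[s, 1]; ay <- ring[s, 2]
    bx <- ring[s + 1, 1]; by <- ring[s + 1, 2]
    cross <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
    seg2 <- (bx - ax)^2 + (by - ay)^2
    dot <- (x - ax) * (bx - ax) + (y - ay) * (by - ay)
    on <- abs(cross) <= eps * max(1, sqrt(seg2)) & dot >= -eps & dot <= seg2 + eps
    out <- out | on
  }
  out
}

# closed containment: interior or boundary
point_in_poly_closed <- function(x, y, ring) {
  pts <- cbind(x, y)
  mgcv::in.out(ring, pts) | point_on_ring(x, y, ring)
}

#' Classify points into shopping zones
#'
#' Boundary points belong to the innermost zone whose closed polygon contains
#' them, so a point exactly on the neighborhood boundary is `neighborhood`.
#'
#' @param x,y coordinate vectors (miles), or `x` a two-column matrix.
#' @param zones a [zone_partition()].
#' @return character vector of zone labels.
#' @export
classify_zone <- function(x, y = NULL, zones) {
  if (!inherits(zones, "zone_partition"))
    stop_fmt("partition error: `zones` must be a zone_partition")
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  out <- rep("suburbs", length(x))
  in_city <- point_in_poly_closed(x, y, zones$city)
  out[in_city] <- "city"
  in_nb <- point_in_poly_closed(x, y, zones$neighborhood)
  out[in_nb] <- "neighborhood"
  out
}

# ---- road network -----------------------------------------------------------

#' Build a road network
#'
#' An undirected graph with planar node coordinates and positive edge lengths
#' in miles.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`.
#' @param edges data.frame with columns `from`, `to` and optionally `length`;
#'   missing lengths are computed from node coordinates.
#' @return an object of class `road_network` wrapping an igraph graph.
#' @export
road_network <- function(nodes, edges) {
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$id)) stop_fmt("duplicate node ids in road network")
  miss <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(miss))
    stop_fmt("edges reference unknown nodes: %s", paste(head(miss, 5), collapse = ", "))
  if (is.null(edges$length) || anyNA(edges$length)) {
    xi <- nodes$x[match(edges$from, nodes$id)]; yi <- nodes$y[match(edges$from, nodes$id)]
    xj <- nodes$x[match(edges$to, nodes$id)];   yj <- nodes$y[match(edges$to, nodes$id)]
    len <- sqrt((xi - xj)^2 + (yi - yj)^2)
    if (is.null(edges$length)) edges$length <- len
    else edges$length[is.na(edges$length)] <- len[is.na(edges$length)]
  }
  if (any(edges$length <= 0))
    stop_fmt("all edge lengths must be positive (found %d nonpositive)",
             sum(edges$length <= 0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$length),
    directed = FALSE,
    vertices = data.frame(name = nodes$id)
  )
  structure(list(graph = g, nodes = nodes[, c("id", "x", "y")]),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network: %d nodes, %d edges, total %.1f mi>\n",
              nrow(x$nodes), igraph::ecount(x$graph),
              sum(igraph::E(x$graph)$weight)))
  invisible(x)
}

#' Shortest network distance between two nodes
#'
#' Length (miles) of the minimum-total-length path; symmetric in its
#' arguments.
#'
#' @param net a [road_network()].
#' @param a,b node ids.
#' @return distance in miles.
#' @export
shortest_path_distance <- function(net, a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!all(c(a, b) %in% net$nodes$id))
    stop_fmt("unknown node id: %s",
             paste(setdiff(c(a, b), net$nodes$id), collapse = ", "))
  d <- igraph::distances(net$graph, v = a, to = b, weights = igraph::E(net$graph)$weight)
  if (!is.finite(d[1, 1]))
    stop_fmt("unreachable error: no path between nodes %s and %s", a, b)
  unname(d[1, 1])
}

#' Snap points to the nearest network node
#'
#' @param net a [road_network()].
#' @param x,y coordinates (miles).
#' @param radius maximum snapping distance in miles.
#' @param ids labels used in error messages.
#' @return character vector of node ids.
#' @export
snap_to_network <- function(net, x, y, radius = 0.25, ids = seq_along(x)) {
  nx <- net$nodes$x; ny <- net$nodes$y
  out <- character(length(x))
  for (i in seq_along(x)) {
    d2 <- (nx - x[i])^2 + (ny - y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > radius)
      stop_fmt("snapping error: feature %s is %.3f mi from the nearest network node (radius %.2f)",
               ids[i], sqrt(d2[j]), radius)
    out[i] <- net$nodes$id[j]
  }
  out
}

#' Origin-destination distance matrix
#'
#' Shortest network distances (miles) from every house to every store, after
#' snapping both to their nearest network nodes.
#'
#' @param net a [road_network()].
#' @param houses data.frame with `id`, `x`, `y` (column `node` reused if present).
#' @param stores data.frame with `id`, `x`, `y` (column `node` reused if present).
#' @param snap_radius snapping radius in miles.
#' @return numeric matrix (houses x stores) with id dimnames, class `od_matrix`.
#' @export
build_od_matrix <- function(net, houses, stores, snap_radius = 0.25) {
  hn <- houses$node %||% snap_to_network(net, houses$x, houses$y, snap_radius, houses$id)
  sn <- stores$node %||% snap_to_network(net, stores$x, stores$y, snap_radius, stores$id)
  hu <- unique(hn); su <- unique(sn)
  d <- igraph::distances(net$graph, v = hu, to = su,
                         weights = igraph::E(net$graph)$weight)
  if (any(!is.finite(d)))
    stop_fmt("unreachable error: some house/store pairs are not connected")
  m <- d[match(hn, hu), match(sn, su), drop = FALSE]
  dimnames(m) <- list(as.character(houses$id), as.character(stores$id))
  attr(m, "house_node") <- setNames(hn, houses$id)
  attr(m, "store_node") <- setNames(sn, stores$id)
  class(m) <- c("od_matrix", class(m))
  m
}

#' Write / read an OD matrix as CSV
#'
#' Long format with columns `house_id`, `store_id`, `distance_miles`.
#' @param od an `od_matrix`.
#' @param path file path.
#' @export
write_od_csv <- function(od, path) {
  long <- data.frame(
    house_id = rep(rownames(od), times = ncol(od)),
    store_id = rep(colnames(od), each = nrow(od)),
    distance_miles = as.vector(od)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_od_csv
#' @export
read_od_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  hs <- unique(long$house_id); ss <- unique(long$store_id)
  m <- matrix(NA_real_, length(hs), length(ss), dimnames = list(hs, ss))
  m[cbind(match(long$house_id, hs), match(long$store_id, ss))] <- long$distance_miles
  if (anyNA(m)) stop_fmt("OD csv is not a complete house x store table")
  class(m) <- c("od_matrix", class(m))
  m
}

# ---- environment loading ----------------------------------------------------

#' Load the spatial environment from GeoJSON files
#'
#' Reads houses, stores, roads and zone polygons, builds the road network,
#' snaps houses and stores to it, verifies connectivity over all referenced
#' nodes, and annotates each store with its shopping zone.
#'
#' @param paths named list or vector with entries `houses`, `stores`, `roads`,
#'   `zones` (file paths), or a directory containing `houses.geojson`,
#'   `stores.geojson`, `roads.geojson`, `zones.geojson`.
#' @param store_types allowed store-type taxonomy.
#' @param snap_radius snapping radius in miles.
#' @return a list of class `fabm_env`: `network`, `houses`, `stores`, `zones`.
#' @export
load_environment <- function(paths, store_types = default_store_types(),
                             snap_radius = 0.25) {
  if (length(paths) == 1 && dir.exists(paths[[1]])) {
    d <- paths[[1]]
    paths <- list(houses = file.path(d, "houses.geojson"),
                  stores = file.path(d, "stores.geojson"),
                  roads = file.path(d, "roads.geojson"),
                  zones = file.path(d, "zones.geojson"))
  }
  houses <- geojson_points(read_geojson(paths$houses),
                           required = c("id", "tract_id"), what = "house")
  stores <- geojson_points(read_geojson(paths$stores),
                           required = c("id", "store_type"), what = "store")
  bad <- setdiff(unique(stores$store_type), store_types)
  if (length(bad))
    stop_fmt("schema error: unknown store_type(s): %s", paste(bad, collapse = ", "))
  rings <- geojson_polygons(read_geojson(paths$zones))
  if (is.null(rings$neighborhood) || is.null(rings$city))
    stop_fmt("schema error: zones file must contain polygons with level 'neighborhood' and 'city'")
  zones <- zone_partition(rings$neighborhood, rings$city)

  net <- network_from_lines(geojson_lines(read_geojson(paths$roads)))
  houses$node <- snap_to_network(net, houses$x, houses$y, snap_radius, houses$id)
  stores$node <- snap_to_network(net, stores$x, stores$y, snap_radius, stores$id)

  comp <- igraph::components(net$graph)
  used <- unique(c(houses$node, stores$node))
  used_comp <- unique(comp$membership[used])
  if (length(used_comp) > 1) {
    sizes <- table(comp$membership[used])
    orphan <- names(sizes)[sizes < max(sizes)]
    stop_fmt("connectivity error: houses/stores fall in %d disconnected components (orphaned components: %s)",
             length(used_comp), paste(orphan, collapse = ", "))
  }
  stores$zone <- classify_zone(stores$x, stores$y, zones)
  houses$id <- as.character(houses$id); stores$id <- as.character(stores$id)
  structure(list(network = net, houses = houses, stores = stores, zones = zones),
            class = "fabm_env")
}

#' @export
print.fabm_env <- function(x, ...) {
  cat(sprintf("<fabm_env: %d houses, %d stores (%s), %d road nodes>\n",
              nrow(x$houses), nrow(x$stores),
              paste(sprintf("%s=%d", names(table(x$stores$zone)),
                            as.integer(table(x$stores$zone))), collapse = " "),
              nrow(x$network$nodes)))
  invisible(x)
}

# Build a road_network from a list of polylines, deduplicating nodes on
# rounded coordinates and splitting each polyline into unit edges. A polyline
# with an explicit total `length` has it distributed over segments in
# proportion to their Euclidean lengths.
network_from_lines <- function(lines, digits = 7) {
  key <- function(m) paste(round(m[, 1], digits), round(m[, 2], digits))
  all_pts <- do.call(rbind, lapply(lines, `[[`, "coords"))
  ks <- key(all_pts)
  keep <- !duplicated(ks)
  nodes <- data.frame(id = as.character(seq_len(sum(keep))),
                      x = all_pts[keep, 1], y = all_pts[keep, 2])
  lut <- setNames(nodes$id, ks[keep])
  edges <- do.call(rbind, lapply(lines, function(ln) {
    m <- ln$coords
    k <- key(m)
    seg <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    len <- seg
    if (!is.null(ln$length)) len <- seg / sum(seg) * as.numeric(ln$length)
    data.frame(from = lut[k[-length(k)]], to = lut[k[-1]], length = len)
  }))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  dup <- duplicated(cbind(pmin(edges$from, edges$to), pmax(edges$from, edges$to)))
  road_network(nodes, edges[!dup, , drop = FALSE])
}
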