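#' The 20-joint depth-sensor skeleton
#'
#' Joint taxonomy used throughout the package: the classic 20-joint
#' depth-sensor skeleton whose parent links form a kinematic tree rooted at
#' the hip center. Orientation quaternions are expressed in the coordinate
#' frame of the parent joint; joints at the very end of a kinematic chain
#' carry no orientation of their own (it is defined by their parent).
#'
#' @format A data frame with 20 rows and columns `joint` (name), `parent`
#'   (name of parent joint, `NA` for the root) and `end_joint` (logical,
#'   `TRUE` for joints that carry no orientation of their own).
#' @export
kinect_joints <- local({
  j <- c(
    "HipCenter", "Spine", "ShoulderCenter", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight"
  )
  p <- c(
    NA, "HipCenter", "Spine", "ShoulderCenter",
    "ShoulderCenter", "ShoulderLeft", "ElbowLeft", "WristLeft",
    "ShoulderCenter", "ShoulderRight", "ElbowRight", "WristRight",
    "HipCenter", "HipLeft", "KneeLeft", "AnkleLeft",
    "HipCenter", "HipRight", "KneeRight", "AnkleRight"
  )
  data.frame(
    joint = j, parent = p,
    end_joint = j %in% c("Head", "HandLeft", "HandRight",
                         "FootLeft", "FootRight"),
    stringsAsFactors = FALSE
  )
})

# Joints excluded from model input: end joints at the very top/bottom of the
# chain whose orientation is defined by their parent. Hands are kept so each
# arm contributes four joints (shoulder, elbow, wrist, hand).
.excluded_joints <- c("Head", "FootLeft", "FootRight")

#' Body-part vertices of the gait graph
#'
#' Fixed vertex order used for all tensor assembly, so that outputs are
#' reproducible bit-for-bit.
#'
#' @return Character vector of the five body-part vertex names.
#' @export
gait_vertices <- function() {
  c("spine", "leg_left", "leg_right", "arm_left", "arm_right")
}

#' Joints assigned to a body-part vertex
#'
#' The 17 non-end joints are partitioned over the five body parts: the spine
#' vertex holds hip center, spine and shoulder center; each leg holds hip,
#' knee and ankle of its side; each arm holds shoulder, elbow, wrist and
#' hand of its side. Order within a vertex is fixed (proximal to distal).
#'
#' @param vertex One of [gait_vertices()].
#' @return Character vector of joint names in their fixed order.
#' @export
joints_for_vertex <- function(vertex) {
  tab <- list(
    spine     = c("HipCenter", "Spine", "ShoulderCenter"),
    leg_left  = c("HipLeft", "KneeLeft", "AnkleLeft"),
    leg_right = c("HipRight", "KneeRight", "AnkleRight"),
    arm_left  = c("ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft"),
    arm_right = c("ShoulderRight", "ElbowRight", "WristRight", "HandRight")
  )
  if (!vertex %in% names(tab)) {
    stop("unknown vertex '", vertex, "'; expected one of: ",
         paste(names(tab), collapse = ", "))
  }
  tab[[vertex]]
}

#' Build the fixed spatiotemporal gait graph
#'
#' The graph G = \{V, Es, Et\} that drives network wiring. Five body-part
#' vertices; spatial adjacency edges connect the spine to each limb; spatial
#' symmetry edges connect the bilateral limb pairs; every vertex carries one
#' temporal self loop. Vertices are partitioned into spine / legs / arms, and
#' each edge partition maps to one shared factor, so the left and right limb
#' of a pair are processed by identical parameters.
#'
#' @return An object of class `st_graph` with elements `vertices`,
#'   `spatial_edges` (2-column matrix with an `etype` attribute of
#'   "adjacency"/"symmetry"), `temporal_edges`, `vertex_partition` (named
#'   vector vertex -> partition), `edge_partition`, and `factor_map`
#'   (partition id -> shared factor id).
#' @export
build_gait_st_graph <- function() {
  v <- gait_vertices()
  spatial <- rbind(
    c("spine", "leg_left"),  c("spine", "leg_right"),
    c("spine", "arm_left"),  c("spine", "arm_right"),
    c("leg_left", "leg_right"), c("arm_left", "arm_right")
  )
  colnames(spatial) <- c("u", "v")
  etype <- c("adjacency", "adjacency", "adjacency", "adjacency",
             "symmetry", "symmetry")
  temporal <- cbind(u = v, v = v)

  vertex_partition <- c(
    spine = "spine", leg_left = "legs", leg_right = "legs",
    arm_left = "arms", arm_right = "arms"
  )
  # one edge partition per (relation, limb pair); each gets one factor
  edge_partition <- c(
    "spine|leg_left" = "adjacency_legs", "spine|leg_right" = "adjacency_legs",
    "spine|arm_left" = "adjacency_arms", "spine|arm_right" = "adjacency_arms",
    "leg_left|leg_right" = "symmetry_legs",
    "arm_left|arm_right" = "symmetry_arms",
    "spine|spine" = "temporal_spine",
    "leg_left|leg_left" = "temporal_legs",
    "leg_right|leg_right" = "temporal_legs",
    "arm_left|arm_left" = "temporal_arms",
    "arm_right|arm_right" = "temporal_arms"
  )
  factor_map <- c(
    spine = "factor_node_spine", legs = "factor_node_legs",
    arms = "factor_node_arms",
    adjacency_legs = "factor_adjacency_legs",
    adjacency_arms = "factor_adjacency_arms",
    symmetry_legs = "factor_symmetry_legs",
    symmetry_arms = "factor_symmetry_arms",
    temporal_spine = "factor_temporal_spine",
    temporal_legs = "factor_temporal_legs",
    temporal_arms = "factor_temporal_arms"
  )
  structure(
    list(
      vertices = v,
      spatial_edges = structure(spatial, etype = etype),
      temporal_edges = temporal,
      vertex_partition = vertex_partition,
      edge_partition = edge_partition,
      factor_map = factor_map
    ),
    class = "st_graph"
  )
}

#' @export
print.st_graph <- function(x, ...) {
  cat("Spatiotemporal gait graph:\n")
  cat("  vertices:      ", paste(x$vertices, collapse = ", "), "\n")
  cat("  spatial edges: ", nrow(x$spatial_edges),
      " (", sum(attr(x$spatial_edges, "etype") == "adjacency"),
      " adjacency, ", sum(attr(x$spatial_edges, "etype") == "symmetry"),
      " symmetry)\n", sep = "")
  cat("  temporal edges:", nrow(x$temporal_edges), "self loops\n")
  cat("  vertex partitions:",
      paste(unique(x$vertex_partition), collapse = ", "), "\n")
  invisible(x)
}

# number of joints feeding a vertex (3 for spine/legs, 4 for arms)
.vertex_rank <- function(vertex) length(joints_for_vertex(vertex))
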