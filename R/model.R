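#' One-degree-of-freedom joint
#'
#' A revolute or prismatic joint coupling a parent link to a child link.
#' The joint frame coincides with the child link frame: \code{origin} and
#' \code{R_off} give the pose of the child frame in the parent frame at
#' zero joint position, and \code{axis} is expressed in the child frame.
#'
#' @param name joint name.
#' @param parent,child link indices (1-based, base link is 1).
#' @param type \code{"revolute"} or \code{"prismatic"}.
#' @param axis unit 3-vector in child-frame coordinates.
#' @param origin child origin in the parent frame at zero position (m).
#' @param R_off child orientation in the parent frame at zero position.
#' @param limits numeric \code{c(min, max)} position limits (rad or m);
#'   may be infinite.
#' @return object of class \code{"model_joint"}.
#' @export
model_joint <- function(name, parent, child, type = c("revolute", "prismatic"),
                        axis = c(0, 0, 1), origin = c(0, 0, 0),
                        R_off = diag(3), limits = c(-Inf, Inf)) {
  type <- match.arg(type)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) stop("joint '", name, "': axis must be a unit vector")
  if (!(limits[1] < limits[2]))
    stop("joint '", name, "': limits must satisfy min < max")
  check_rotation(R_off)
  structure(list(name = name, parent = as.integer(parent),
                 child = as.integer(child), type = type,
                 axis = as.numeric(axis), origin = as.numeric(origin),
                 R_off = R_off, limits = as.numeric(limits)),
            class = "model_joint")
}

#' Motion freedom subspace of a joint
#'
#' The 6-vector S mapping the scalar joint rate to the relative
#' child-frame 6-velocity: \code{(axis, 0)} for prismatic,
#' \code{(0, axis)} for revolute.  Its transpose projects the joint wrench
#' onto the joint torque.
#'
#' @param joint a \code{model_joint}.
#' @return numeric 6-vector.
#' @export
joint_motion_subspace <- function(joint) {
  if (joint$type == "prismatic") c(joint$axis, 0, 0, 0) else c(0, 0, 0, joint$axis)
}

#' Pose of the child frame in the parent frame at joint position s
#'
#' @param joint a \code{model_joint}.
#' @param s joint position (rad or m).
#' @return \code{spatial_transform} of the child frame in the parent frame.
#' @export
joint_transform <- function(joint, s) {
  if (joint$type == "revolute") {
    spatial_transform(joint$R_off %*% rot_axis_angle(joint$axis, s), joint$origin)
  } else {
    spatial_transform(joint$R_off,
                      joint$origin + as.numeric(joint$R_off %*% (joint$axis * s)))
  }
}

#' Rigid multi-body tree model
#'
#' An ordered set of links (spatial inertias) connected by one-DoF joints,
#' rooted at a floating base.  Link 1 is the base; joint \code{j} couples
#' parent \code{lambda(j+1)} to child link \code{j+1}, so a model with
#' \code{N_B} links has \code{n = N_B - 1} joints.  The base has no parent
#' joint.
#'
#' @param links list of \code{list(name =, inertia = spatial_inertia)}.
#' @param joints list of \code{\link{model_joint}}; joint \code{j} must have
#'   \code{child == j + 1} and \code{parent < child}.
#' @return object of class \code{"multibody_model"} with elements
#'   \code{links}, \code{joints}, \code{parent} (parent-link map, \code{NA}
#'   for the base) and \code{children} (child-link map).
#' @export
multibody_model <- function(links, joints = list()) {
  nb <- length(links)
  n <- length(joints)
  if (n != nb - 1L)
    stop("a tree with ", nb, " links needs ", nb - 1L, " joints, got ", n)
  parent <- rep(NA_integer_, nb)
  for (j in seq_len(n)) {
    jt <- joints[[j]]
    if (jt$child != j + 1L)
      stop("joint ", j, " must have child link ", j + 1L,
           " (topological numbering), got ", jt$child)
    if (jt$parent == jt$child)
      stop("joint '", jt$name, "': child link equals parent link")
    if (jt$parent >= jt$child || jt$parent < 1L)
      stop("joint '", jt$name, "': parent must precede child in topological order")
    parent[jt$child] <- jt$parent
  }
  children <- lapply(seq_len(nb), function(i) which(parent == i))
  structure(list(links = links, joints = joints,
                 parent = parent, children = children),
            class = "multibody_model")
}

#' @export
print.multibody_model <- function(x, ...) {
  cat("multibody model:", n_links(x), "links,", n_joints(x),
      "one-DoF joints, floating base '", x$links[[1]]$name, "'\n", sep = "")
  invisible(x)
}

#' Number of links / joints in a model
#' @param model a \code{multibody_model}.
#' @return integer count.
#' @export
n_links <- function(model) length(model$links)

#' @rdname n_links
#' @export
n_joints <- function(model) length(model$joints)

#' Find a link index by name
#' @param model a \code{multibody_model}.
#' @param name link name.
#' @return integer index.
#' @export
link_index <- function(model, name) {
  i <- match(name, vapply(model$links, `[[`, "", "name"))
  if (is.na(i)) stop("unknown link '", name, "'")
  i
}

## Links on the path from the base to link i (inclusive), base first.
path_to_base <- function(model, i) {
  p <- integer(0)
  while (!is.na(i)) {
    p <- c(i, p)
    i <- model$parent[i]
  }
  p
}

xml_num <- function(s, n) {
  v <- as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (length(v) != n || anyNA(v)) stop("cannot parse numeric attribute: '", s, "'")
  v
}

#' Read a URDF model (supported subset)
#'
#' Parses links with inertial blocks and one-DoF joints (revolute,
#' prismatic; continuous is mapped to revolute with infinite limits) from a
#' URDF XML string or file.  Visual/collision geometry is ignored.  Links
#' are renumbered topologically with the root (the link that is never a
#' joint child) as the floating base.
#'
#' @param x URDF XML as a string, or a file path.
#' @return a \code{\link{multibody_model}}.
#' @export
parse_urdf <- function(x) {
  doc <- if (length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  link_nodes <- xml2::xml_find_all(doc, ".//link")
  if (length(link_nodes) == 0L) stop("URDF contains no <link> elements")
  raw_links <- lapply(link_nodes, function(node) {
    name <- xml2::xml_attr(node, "name")
    inode <- xml2::xml_find_first(node, "./inertial")
    if (inherits(inode, "xml_missing"))
      stop("link '", name, "' is missing its <inertial> element")
    mnode <- xml2::xml_find_first(inode, "./mass")
    if (inherits(mnode, "xml_missing"))
      stop("link '", name, "' is missing <mass> in <inertial>")
    mass <- as.numeric(xml2::xml_attr(mnode, "value"))
    onode <- xml2::xml_find_first(inode, "./origin")
    com <- c(0, 0, 0); rpy <- c(0, 0, 0)
    if (!inherits(onode, "xml_missing")) {
      if (!is.na(xml2::xml_attr(onode, "xyz")))
        com <- xml_num(xml2::xml_attr(onode, "xyz"), 3)
      if (!is.na(xml2::xml_attr(onode, "rpy")))
        rpy <- xml_num(xml2::xml_attr(onode, "rpy"), 3)
    }
    tnode <- xml2::xml_find_first(inode, "./inertia")
    if (inherits(tnode, "xml_missing"))
      stop("link '", name, "' is missing <inertia> in <inertial>")
    g <- function(a) as.numeric(xml2::xml_attr(tnode, a))
    I_com <- matrix(c(g("ixx"), g("ixy"), g("ixz"),
                      g("ixy"), g("iyy"), g("iyz"),
                      g("ixz"), g("iyz"), g("izz")), 3L, 3L)
    Rc <- rot_rpy(rpy)
    I_o <- inertia_at_origin(Rc %*% I_com %*% t(Rc), mass, com)
    list(name = name, inertia = spatial_inertia(mass, com, I_o))
  })
  link_names <- vapply(raw_links, `[[`, "", "name")

  joint_nodes <- xml2::xml_find_all(doc, ".//joint")
  raw_joints <- lapply(joint_nodes, function(node) {
    name <- xml2::xml_attr(node, "name")
    type <- xml2::xml_attr(node, "type")
    if (type == "fixed") return(NULL)
    if (!type %in% c("revolute", "prismatic", "continuous"))
      stop("joint '", name, "': unsupported joint type '", type, "'")
    parent <- xml2::xml_attr(xml2::xml_find_first(node, "./parent"), "link")
    child <- xml2::xml_attr(xml2::xml_find_first(node, "./child"), "link")
    if (is.na(parent) || is.na(child))
      stop("joint '", name, "': missing <parent> or <child>")
    if (identical(parent, child))
      stop("joint '", name, "': child link equals parent link")
    onode <- xml2::xml_find_first(node, "./origin")
    xyz <- c(0, 0, 0); rpy <- c(0, 0, 0)
    if (!inherits(onode, "xml_missing")) {
      if (!is.na(xml2::xml_attr(onode, "xyz")))
        xyz <- xml_num(xml2::xml_attr(onode, "xyz"), 3)
      if (!is.na(xml2::xml_attr(onode, "rpy")))
        rpy <- xml_num(xml2::xml_attr(onode, "rpy"), 3)
    }
    anode <- xml2::xml_find_first(node, "./axis")
    axis <- if (inherits(anode, "xml_missing")) c(1, 0, 0)
            else xml_num(xml2::xml_attr(anode, "xyz"), 3)
    lims <- c(-Inf, Inf)
    lnode <- xml2::xml_find_first(node, "./limit")
    if (type != "continuous" && !inherits(lnode, "xml_missing")) {
      lo <- suppressWarnings(as.numeric(xml2::xml_attr(lnode, "lower")))
      up <- suppressWarnings(as.numeric(xml2::xml_attr(lnode, "upper")))
      if (!is.na(lo)) lims[1] <- lo
      if (!is.na(up)) lims[2] <- up
    }
    list(name = name, type = if (type == "continuous") "revolute" else type,
         parent = parent, child = child, axis = axis / sqrt(sum(axis^2)),
         origin = xyz, R_off = rot_rpy(rpy), limits = lims)
  })
  raw_joints <- Filter(Negate(is.null), raw_joints)

  for (j in raw_joints) {
    if (!j$parent %in% link_names) stop("joint '", j$name, "': unknown parent link '", j$parent, "'")
    if (!j$child %in% link_names) stop("joint '", j$name, "': unknown child link '", j$child, "'")
  }
  child_set <- vapply(raw_joints, `[[`, "", "child")
  if (anyDuplicated(child_set))
    stop("link '", child_set[duplicated(child_set)][1],
         "' is the child of more than one joint (cycle or non-tree topology)")
  roots <- setdiff(link_names, child_set)
  if (length(roots) != 1L)
    stop("topology is not a single tree: found ", length(roots), " root links")

  # breadth-first renumbering from the root
  order_names <- roots
  frontier <- roots
  while (length(frontier) > 0L) {
    nxt <- child_set[vapply(raw_joints, `[[`, "", "parent") %in% frontier]
    order_names <- c(order_names, nxt)
    frontier <- nxt
  }
  if (length(order_names) != length(link_names))
    stop("topology contains a cycle or disconnected links")
  idx <- match(order_names, link_names)
  links <- raw_links[idx]
  # joints sorted so that joint j has child link j+1
  joints <- vector("list", length(raw_joints))
  for (j in raw_joints) {
    ci <- match(j$child, order_names)
    joints[[ci - 1L]] <- model_joint(j$name, match(j$parent, order_names), ci,
                                     j$type, j$axis, j$origin, j$R_off, j$limits)
  }
  multibody_model(links, joints)
}

#' Serialize a model to URDF XML
#'
#' Writes the supported subset (inertials at the centre of mass, revolute
#' and prismatic joints); \code{parse_urdf(write_urdf(m))} reproduces
#' \code{m} up to numerical round-off.
#'
#' @param model a \code{multibody_model}.
#' @param name robot name attribute.
#' @return a single URDF XML string.
#' @export
write_urdf <- function(model, name = "model") {
  num <- function(x) paste(format(x, digits = 17, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  out <- c(sprintf('<robot name="%s">', name))
  for (lk in model$links) {
    m <- lk$inertia
    com <- m$h / m$mass
    S <- skew(com)
    I_c <- m$inertia + m$mass * (S %*% S)  # back to COM for URDF convention
    out <- c(out,
      sprintf('  <link name="%s">', lk$name),
      '    <inertial>',
      sprintf('      <origin xyz="%s" rpy="0 0 0"/>', num(com)),
      sprintf('      <mass value="%s"/>', num(m$mass)),
      sprintf('      <inertia ixx="%s" ixy="%s" ixz="%s" iyy="%s" iyz="%s" izz="%s"/>',
              num(I_c[1, 1]), num(I_c[1, 2]), num(I_c[1, 3]),
              num(I_c[2, 2]), num(I_c[2, 3]), num(I_c[3, 3])),
      '    </inertial>',
      '  </link>')
  }
  for (jt in model$joints) {
    rpy <- rev(euler_zyx(jt$R_off))  # (roll, pitch, yaw)
    type <- if (jt$type == "revolute" && all(is.infinite(jt$limits)))
      "continuous" else jt$type
    out <- c(out,
      sprintf('  <joint name="%s" type="%s">', jt$name, type),
      sprintf('    <parent link="%s"/>', model$links[[jt$parent]]$name),
      sprintf('    <child link="%s"/>', model$links[[jt$child]]$name),
      sprintf('    <origin xyz="%s" rpy="%s"/>', num(jt$origin), num(rpy)),
      sprintf('    <axis xyz="%s"/>', num(jt$axis)))
    if (type != "continuous")
      out <- c(out, sprintf('    <limit lower="%s" upper="%s"/>',
                            num(jt$limits[1]), num(jt$limits[2])))
    out <- c(out, '  </joint>')
  }
  paste(c(out, '</robot>'), collapse = "\n")
}

#' Dump / load a model as JSON
#'
#' Lossless fixture format for tests and the command-line tools.
#'
#' @param model a \code{multibody_model}.
#' @param path optional file path; if missing the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    links = lapply(model$links, function(l)
      list(name = l$name, mass = l$inertia$mass, h = l$inertia$h,
           inertia = l$inertia$inertia)),
    joints = lapply(model$joints, function(j)
      list(name = j$name, parent = j$parent, child = j$child, type = j$type,
           axis = j$axis, origin = j$origin, R_off = j$R_off,
           limits = j$limits)))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param x JSON string or file path produced by \code{model_to_json}.
#' @export
model_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  links <- lapply(obj$links, function(l)
    list(name = l$name,
         inertia = spatial_inertia(l$mass, unlist(l$h) / l$mass,
                                   matrix(unlist(l$inertia), 3L, 3L))))
  joints <- lapply(obj$joints, function(j) {
    lim <- unlist(lapply(j$limits, function(v)
      if (is.character(v)) as.numeric(v) else v))
    model_joint(j$name, j$parent, j$child, j$type, unlist(j$axis),
                unlist(j$origin), matrix(unlist(j$R_off), 3L, 3L), lim)
  })
  multibody_model(links, joints)
}
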