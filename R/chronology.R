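# Species/duplication event trees and dating of whole-genome
# duplications from modal Ks observations.
#
# The tree is rooted; tips are genomes; internal nodes are speciations
# or duplication events (WGD/WGT). Duplication nodes are *unary*: they
# sit on a lineage branch and do not bifurcate the species tree. Every
# branch length (in Ks units) is an unknown solved from observed modal
# Ks values by least squares; a single root calibration (in Mya)
# converts Ks path lengths to ages.

#' Construct a species/duplication event tree
#'
#' @param nodes tibble with columns `node` (label), `parent` (label, `NA`
#'   for the root), `type` (one of `"tip"`, `"speciation"`, `"wgd"`,
#'   `"wgt"`), and optionally `length` (branch length above the node, in
#'   Ks units; `NA` where unknown).
#' @return an `event_tree` object.
#' @export
event_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("node", "parent", "type") %in% names(nodes)))
  if (!"length" %in% names(nodes)) nodes$length <- NA_real_
  if (anyDuplicated(nodes$node)) abort("duplicate node labels")
  root <- nodes$node[is.na(nodes$parent)]
  if (length(root) != 1) abort("tree must have exactly one root")
  if (!all(stats::na.omit(nodes$parent) %in% nodes$node)) abort("unknown parent label")
  # reachability from the root
  kids <- split(nodes$node, nodes$parent)[unique(stats::na.omit(nodes$parent))]
  seen <- root; frontier <- root
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  if (!setequal(seen, nodes$node)) abort("tree has nodes unreachable from the root")
  n_children <- table(factor(nodes$parent, levels = nodes$node))
  dup <- nodes$type %in% c("wgd", "wgt") & nodes$node != root
  if (any(n_children[nodes$node[dup]] != 1))
    abort("duplication nodes must be unary (exactly one child)")
  if (any(nodes$type == "tip" & n_children[nodes$node] > 0))
    abort("tips cannot have children")
  structure(list(nodes = nodes, root = root), class = "event_tree")
}

#' @export
print.event_tree <- function(x, ...) {
  cat("<event_tree>", nrow(x$nodes), "nodes,", length(tree_tips(x)),
      "tips, root =", x$root, "\n")
  invisible(x)
}

tree_tips <- function(tree, below = NULL) {
  nd <- tree$nodes
  tips <- nd$node[nd$type == "tip"]
  if (is.null(below)) return(tips)
  tips[vapply(tips, function(t) below %in% ancestors_of(tree, t), logical(1))]
}

# ancestors of `node`, nearest first, up to and including the root
ancestors_of <- function(tree, node) {
  nd <- tree$nodes
  out <- character(0)
  cur <- nd$parent[nd$node == node]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- nd$parent[nd$node == cur]
  }
  out
}

tree_mrca <- function(tree, a, b) {
  aa <- c(a, ancestors_of(tree, a))
  bb <- c(b, ancestors_of(tree, b))
  aa[aa %in% bb][1]
}

# nodes whose *branch above* lies on the path node -> ancestor
path_nodes <- function(tree, node, ancestor) {
  if (node == ancestor) return(character(0))
  anc <- ancestors_of(tree, node)
  if (!ancestor %in% anc) abort(sprintf("'%s' is not ancestral to '%s'", ancestor, node))
  c(node, anc[seq_len(match(ancestor, anc) - 1)])
}

path_length <- function(tree, node, ancestor) {
  p <- path_nodes(tree, node, ancestor)
  sum(tree$nodes$length[match(p, tree$nodes$node)])
}

#' Build the linear system relating branch lengths to modal Ks observations
#'
#' Each ortholog observation between tips X and Y contributes a row
#' summing the branches on both tip-to-MRCA paths. Each paralog
#' observation (tip, duplication event E) contributes a row equal to
#' twice the tip-to-E path: the two post-duplication paralog lineages
#' reside in one genome and are approximated by the same branches.
#' "Old ortholog" observations through the root duplication are encoded
#' as `kind = "ortholog_root"`, forcing the MRCA to the root.
#'
#' @param tree an [event_tree()].
#' @param obs tibble with columns `kind` (`"ortholog"`, `"paralog"`, or
#'   `"ortholog_root"`), `tip_a`, `tip_b` (second tip, or event node for
#'   paralog rows), `observed`.
#' @return list with design matrix `A` (rows = observations, columns =
#'   branches named by child node) and response vector `d`.
#' @export
build_system <- function(tree, obs) {
  stopifnot(inherits(tree, "event_tree"))
  obs <- as_tibble(obs)
  if (nrow(obs) == 0) abort("no observations")
  branches <- tree$nodes$node[!is.na(tree$nodes$parent)]
  A <- matrix(0, nrow = nrow(obs), ncol = length(branches),
              dimnames = list(NULL, branches))
  for (i in seq_len(nrow(obs))) {
    k <- obs$kind[i]
    if (k %in% c("ortholog", "ortholog_root")) {
      m <- if (k == "ortholog_root") tree$root else
        tree_mrca(tree, obs$tip_a[i], obs$tip_b[i])
      p <- c(path_nodes(tree, obs$tip_a[i], m), path_nodes(tree, obs$tip_b[i], m))
      A[i, p] <- A[i, p] + 1
    } else if (k == "paralog") {
      ev <- obs$tip_b[i]
      if (!ev %in% c(ancestors_of(tree, obs$tip_a[i])))
        abort(sprintf("event '%s' is not ancestral to tip '%s'", ev, obs$tip_a[i]))
      p <- path_nodes(tree, obs$tip_a[i], ev)
      A[i, p] <- A[i, p] + 2
    } else {
      abort(sprintf("unknown observation kind '%s'", k))
    }
  }
  list(A = A, d = obs$observed)
}

#' Solve branch lengths by least squares
#'
#' @param A design matrix from [build_system()].
#' @param d observed modal Ks vector.
#' @return list with `lengths` (named by branch child node), `residual`
#'   (Euclidean norm of `A b - d`), and `clipped` (`TRUE` if any solved
#'   length was negative and clipped to zero).
#' @export
solve_branch_lengths <- function(A, d) {
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    unresolved <- colnames(A)[-seq_len(qr_A$rank)]
    abort(paste0("system is under-determined; unresolved branches: ",
                 paste(colnames(A)[qr_A$pivot[-seq_len(qr_A$rank)]], collapse = ", ")))
  }
  b <- qr.coef(qr_A, d)
  clipped <- any(b < 0)
  if (clipped) {
    warn("negative solved branch lengths clipped to 0")
    b <- pmax(b, 0)
  }
  list(lengths = setNames(as.numeric(b), colnames(A)),
       residual = sqrt(sum((A %*% b - d)^2)),
       clipped = clipped)
}

#' Convert solved branch lengths to node ages and per-branch rates
#'
#' Ages are assigned by per-lineage proportional scaling: for a node *n*,
#' `age(n) = cal_age * mean over descendant tips t of Ks(t -> n) / Ks(t -> root)`.
#' The calibration node is the root; tips are at age 0. Each branch's
#' rate is its Ks length divided by its time duration.
#'
#' @param tree an [event_tree()].
#' @param lengths named branch lengths (from [solve_branch_lengths()]),
#'   or `NULL` to use lengths stored in the tree.
#' @param calibration_age root age in Mya.
#' @return a `wgd_chronology` object; see [tidy.wgd_chronology()].
#' @export
assign_dates <- function(tree, lengths = NULL, calibration_age = 58) {
  stopifnot(inherits(tree, "event_tree"))
  nd <- tree$nodes
  if (!is.null(lengths)) {
    if (is.list(lengths) && !is.null(lengths$lengths)) {
      fit <- lengths
      lengths <- lengths$lengths
    } else fit <- NULL
    nd$length[match(names(lengths), nd$node)] <- lengths
  } else fit <- NULL
  tree <- event_tree(nd)
  tips <- tree_tips(tree)
  root_ks <- setNames(vapply(tips, function(t) path_length(tree, t, tree$root), numeric(1)), tips)
  if (any(root_ks <= 0)) abort("zero-length root-to-tip path; rates are degenerate")
  age <- setNames(rep(NA_real_, nrow(nd)), nd$node)
  for (n in nd$node) {
    if (nd$type[nd$node == n] == "tip") { age[n] <- 0; next }
    desc <- tree_tips(tree, below = n)
    if (n == tree$root) desc <- tips
    age[n] <- calibration_age *
      mean(vapply(desc, function(t) path_length(tree, t, n), numeric(1)) / root_ks[desc])
  }
  age[tree$root] <- calibration_age
  age_of <- age
  nodes_out <- nd |> mutate(age = unname(age_of[.data$node]))
  branches_out <- nodes_out |>
    filter(!is.na(.data$parent)) |>
    mutate(duration = unname(age_of[.data$parent]) - .data$age,
           rate = ifelse(.data$duration > 0, .data$length / .data$duration, NA_real_)) |>
    select("node", "parent", "length", "duration", "rate")
  structure(list(nodes = nodes_out, branches = branches_out,
                 calibration_age = calibration_age,
                 residual = fit$residual %||% NA_real_,
                 clipped = fit$clipped %||% FALSE),
            class = "wgd_chronology")
}

#' @export
print.wgd_chronology <- function(x, ...) {
  cat("<wgd_chronology> calibrated at", x$calibration_age, "Mya\n")
  ev <- x$nodes |> filter(.data$type %in% c("wgd", "wgt", "speciation"))
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %-12s %-10s %6.1f Mya\n", ev$node[i], ev$type[i], ev$age[i]))
  invisible(x)
}

#' Tidy a WGD chronology into one row per node
#'
#' @param x a `wgd_chronology`.
#' @param ... unused.
#' @return tibble with node, type, age (Mya), branch length above the
#'   node (Ks), branch duration (My) and rate (Ks/My).
#' @method tidy wgd_chronology
#' @export
tidy.wgd_chronology <- function(x, ...) {
  x$nodes |>
    left_join(select(x$branches, "node", "duration", "rate"), by = "node") |>
    select("node", "parent", "type", "length", "age", "duration", "rate")
}

#' One-row summary of a WGD chronology fit
#' @param x a `wgd_chronology`.
#' @param ... unused.
#' @return tibble with the calibration age, number of branches, residual
#'   norm of the least-squares solve, and whether clipping occurred.
#' @method glance wgd_chronology
#' @export
glance.wgd_chronology <- function(x, ...) {
  tibble(calibration_age = x$calibration_age,
         n_branches = nrow(x$branches),
         residual = x$residual,
         clipped = x$clipped)
}

#' Solve a chronology end-to-end
#'
#' Convenience wrapper: [build_system()], [solve_branch_lengths()],
#' [assign_dates()].
#' @param tree an [event_tree()] (lengths may be unknown).
#' @param obs modal Ks observation tibble.
#' @param calibration_age root age in Mya.
#' @return a `wgd_chronology`.
#' @export
solve_chronology <- function(tree, obs, calibration_age = 58) {
  sys <- build_system(tree, obs)
  fit <- solve_branch_lengths(sys$A, sys$d)
  assign_dates(tree, fit, calibration_age = calibration_age)
}

#' Generate a random event tree for simulation studies
#'
#' A random rooted binary topology over `n_tips` genomes, with
#' `n_dups` unary duplication nodes inserted on random branches, and
#' branch lengths drawn uniformly.
#'
#' @param n_tips number of tip genomes (>= 2).
#' @param n_dups number of duplication nodes to insert.
#' @param seed integer seed.
#' @param length_range range of branch lengths (Ks units).
#' @return an [event_tree()] with known lengths.
#' @export
random_event_tree <- function(n_tips = 5, n_dups = 2, seed = 1,
                              length_range = c(0.02, 0.4)) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  # the root is a duplication event (a WGD-rooted species tree) with a
  # single child: root paralog observations are what make the branches
  # incident to the basal speciation identifiable
  nodes <- tibble(node = c("root", "base", "t1", "t2"),
                  parent = c(NA, "root", "base", "base"),
                  type = c("wgd", "speciation", "tip", "tip"))
  n_int <- 0L
  while (sum(nodes$type == "tip") < n_tips) {
    tsel <- sample(nodes$node[nodes$type == "tip"], 1)
    n_int <- n_int + 1L
    inner <- paste0("s", n_int)
    new_tip <- paste0("t", sum(nodes$type == "tip") + 1)
    old_parent <- nodes$parent[nodes$node == tsel]
    nodes <- bind_rows(nodes,
      tibble(node = inner, parent = old_parent, type = "speciation"),
      tibble(node = new_tip, parent = inner, type = "tip"))
    nodes$parent[nodes$node == tsel] <- inner
  }
  # insert unary duplication nodes on random branches
  for (i in seq_len(n_dups)) {
    target <- sample(nodes$node[!is.na(nodes$parent)], 1)
    dn <- paste0("dup", i)
    nodes <- bind_rows(nodes,
      tibble(node = dn, parent = nodes$parent[nodes$node == target],
             type = sample(c("wgd", "wgt"), 1)))
    nodes$parent[nodes$node == target] <- dn
  }
  nodes$length <- ifelse(is.na(nodes$parent), NA_real_,
                         runif(nrow(nodes), length_range[1], length_range[2]))
  event_tree(nodes)
}
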