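# Plain-text interchange: anchors, blocks, observations, event trees.

#' Read a gene-anchor table
#'
#' Tab-delimited with header: `gene_a, chr_a, start_a, end_a, gene_b,
#' chr_b, start_b, end_b, score`, and optionally `ks` (e.g. ingested
#' from an external Ks pipeline).
#'
#' @param path TSV path.
#' @return anchor tibble.
#' @export
read_anchors <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_a", "chr_a", "start_a", "end_a",
            "gene_b", "chr_b", "start_b", "end_b", "score")
  if (!all(need %in% names(df)))
    abort(paste("anchor table must have columns:", paste(need, collapse = ", ")))
  df
}

#' Write synteny blocks as a TSV (anchors list-column dropped)
#' @param blocks block tibble from [chain_anchors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  readr::write_tsv(select(blocks, -dplyr::any_of("anchors")), path, progress = FALSE)
  invisible(path)
}

#' Read / write modal Ks observation tables
#'
#' Columns: `kind` (`ortholog` / `ortholog_root` / `paralog`), `tip_a`,
#' `tip_b` (second tip or event node), `observed`.
#' @param path TSV path.
#' @return observation tibble.
#' @export
read_observations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("kind", "tip_a", "tip_b", "observed") %in% names(df)))
  df
}

#' @rdname read_observations
#' @param obs observation tibble.
#' @export
write_observations <- function(obs, path) {
  readr::write_tsv(obs, path, progress = FALSE)
  invisible(path)
}

#' Serialise an event tree to a bracketed newick-like string
#'
#' Dialect: `label[:type=speciation|wgd|wgt]` on internal nodes, with
#' optional `:length` branch lengths; duplication nodes are unary
#' (single-child groups). Example:
#' `((A:0.1,B:0.2)s1[:type=speciation]:0.05)root[:type=wgd];`
#'
#' @param tree an [event_tree()].
#' @return a single newick string.
#' @export
write_event_newick <- function(tree) {
  nd <- tree$nodes
  kids <- split(nd$node, nd$parent)
  render <- function(n) {
    row <- nd[nd$node == n, ]
    ch <- kids[[n]]
    inner <- if (is.null(ch)) "" else paste0("(", paste(vapply(ch, render, ""), collapse = ","), ")")
    tag <- if (row$type == "tip") "" else sprintf("[:type=%s]", row$type)
    len <- if (is.na(row$parent) || is.na(row$length)) "" else sprintf(":%g", row$length)
    paste0(inner, n, tag, len)
  }
  paste0(render(tree$root), ";")
}

#' Parse the bracketed event-tree newick dialect
#'
#' Counterpart of [write_event_newick()]. This dialect permits unary
#' (single-child) nodes, which standard phylogenetic readers collapse,
#' so it is parsed directly.
#'
#' @param text newick string (or a file path to one).
#' @return an [event_tree()].
#' @export
read_event_newick <- function(text) {
  if (file.exists(text)) text <- paste(readLines(text), collapse = "")
  text <- sub(";\\s*$", "", trimws(text))
  counter <- new.env(); counter$i <- 0
  rows <- list()
  # recursive descent: node := ( "(" node ("," node)* ")" )? label? tag? len?
  parse_node <- function(s, parent) {
    s <- trimws(s)
    children <- character(0)
    rest <- s
    if (startsWith(s, "(")) {
      depth <- 0; split_at <- integer(0)
      chars <- strsplit(s, "")[[1]]
      for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1
        if (chars[i] == ")") { depth <- depth - 1; if (depth == 0) { close_at <- i; break } }
        if (chars[i] == "," && depth == 1) split_at <- c(split_at, i)
      }
      inner <- substr(s, 2, close_at - 1)
      bounds <- c(1, split_at - 1, close_at - 1)
      pieces <- character(0)
      startp <- 2
      for (sp in c(split_at, close_at)) {
        pieces <- c(pieces, substr(s, startp, sp - 1))
        startp <- sp + 1
      }
      rest <- substr(s, close_at + 1, nchar(s))
      children <- pieces
    }
    label <- rest
    type <- NA_character_
    len <- NA_real_
    tag <- regmatches(label, regexpr("\\[:type=[a-z]+\\]", label))
    if (length(tag) == 1 && nchar(tag)) {
      type <- sub("\\[:type=([a-z]+)\\]", "\\1", tag)
      label <- sub("\\[:type=[a-z]+\\]", "", label)
    }
    if (grepl(":", label, fixed = TRUE)) {
      len <- as.numeric(sub("^.*:", "", label))
      label <- sub(":.*$", "", label)
    }
    if (!nzchar(label)) {
      counter$i <- counter$i + 1
      label <- paste0("n", counter$i)
    }
    if (is.na(type)) type <- if (length(children) == 0) "tip" else "speciation"
    rows[[length(rows) + 1]] <<- tibble(node = label, parent = parent,
                                        type = type, length = len)
    for (ch in children) parse_node(ch, label)
    label
  }
  parse_node(text, NA_character_)
  event_tree(bind_rows(rows))
}
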