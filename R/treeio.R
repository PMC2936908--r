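#' Read phylogenetic trees from Newick or Nexus files
#'
#' Reads one or more rooted trees with branch lengths. Nexus TREES blocks
#' with TRANSLATE tables are resolved to full tip labels, and BEAST-style
#' bracketed annotations (`[&...]`, e.g. node metadata on MCC trees) are
#' stripped before parsing so that annotated chronograms and plain trees
#' parse to identical topologies and branch lengths. Tree order in the file
#' is preserved, so posterior samples keep their sample order.
#'
#' @param path path to a tree file.
#' @param format `"auto"` (detect a leading `#NEXUS`), `"newick"`, or
#'   `"nexus"`.
#' @return an object of class `"multiPhylo"` (a list of `"phylo"` trees),
#'   even when the file contains a single tree.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((a:1,b:1):1,c:2);", tf)
#' trees <- read_trees(tf)
#' length(trees)
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)))
      "nexus" else "newick"
  }
  txt <- strip_annotations(txt)
  trees <- if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    res <- tryCatch(ape::read.nexus(tf), error = function(e)
      stop("failed to parse Nexus TREES block: ", conditionMessage(e),
           call. = FALSE))
    if (inherits(res, "phylo")) structure(list(res), class = "multiPhylo")
    else res
  } else {
    parse_newick_lines(txt)
  }
  for (i in seq_along(trees)) {
    tl <- trees[[i]]$tip.label
    if (anyDuplicated(tl))
      stop("duplicate tip labels in tree ", i, ": ",
           paste(unique(tl[duplicated(tl)]), collapse = ", "))
    trees[[i]]$tip.label <- gsub("[ \t]+", "_", tl)
  }
  labsets <- lapply(unclass(trees), function(t) sort(t$tip.label))
  if (length(trees) > 1L &&
      !all(vapply(labsets[-1], identical, logical(1), labsets[[1]])))
    warning("trees in ", path, " do not share an identical tip-label set")
  trees
}

## remove bracketed comments ([&...] BEAST annotations and plain [] Nexus
## comments); branch lengths outside brackets are untouched
strip_annotations <- function(txt) gsub("\\[[^]]*\\]", "", txt, perl = TRUE)

parse_newick_lines <- function(txt) {
  one <- paste(txt, collapse = "\n")
  pieces <- strsplit(one, ";", fixed = TRUE)[[1]]
  pieces <- pieces[grepl("\\(", pieces)]
  if (length(pieces) == 0L) stop("no Newick tree found in input")
  trees <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    s <- pieces[i]
    if (unbalanced_parens(s))
      stop("malformed parenthesis structure in tree ", i)
    tr <- tryCatch(ape::read.tree(text = paste0(trimws(s), ";")),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr))
      stop("failed to parse Newick tree ", i)
    trees[[i]] <- tr
  }
  structure(trees, class = "multiPhylo")
}

unbalanced_parens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  any(depth < 0) || depth[length(depth)] != 0
}

#' Write trees to a Newick file
#'
#' @param trees a `"phylo"` or `"multiPhylo"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Node heights and relative node heights
#'
#' The height of a node is its distance down to its descendant tips; for a
#' non-ultrametric tree the mean over descendant tips is used and a warning
#' is emitted (relative tip-depth spread above 1e-6). Tips have height 0.
#' Relative height divides by the root height, so the root maps to 1 on an
#' ultrametric tree; on a relaxed-clock MCC chronogram the relative height
#' of a node is the relative age of the split.
#'
#' @param tree a rooted `"phylo"` with branch lengths.
#' @return a list with numeric vectors `height` and `relative`, both of
#'   length `Ntip + Nnode` indexed by ape node number, and a logical
#'   `ultrametric`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' node_heights(tr)$relative
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; node heights undefined")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  sumd <- numeric(n + m)
  cnt <- integer(n + m)
  sumd[seq_len(n)] <- depth[seq_len(n)]
  cnt[seq_len(n)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    sumd[p] <- sumd[p] + sumd[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  height <- sumd / cnt - depth
  height[seq_len(n)] <- 0
  root <- n + 1L
  root_h <- height[root]
  tipdepth <- depth[seq_len(n)]
  spread <- diff(range(tipdepth))
  ultra <- root_h > 0 && spread / root_h <= 1e-6
  if (root_h <= 0)
    stop("root height is zero; relative node heights undefined")
  if (!ultra)
    warning(sprintf(
      "tree is not ultrametric (relative tip-depth spread %.3g); %s",
      spread / root_h, "node heights use mean distance to descendant tips"))
  list(height = height, relative = height / root_h, ultrametric = ultra)
}

#' Extract terminal sister-species pairs (cherries)
#'
#' A cherry is an internal node whose children are exactly two tips; its two
#' species are a terminal sister pair and its relative node height is the
#' pair's relative split age. Polytomous nodes whose children are three or
#' more tips are skipped with a warning rather than decomposed into pairs,
#' since any pairing would be arbitrary and would bias split ages.
#'
#' @param tree a rooted `"phylo"` with branch lengths.
#' @return a data frame with columns `tip_a`, `tip_b` (alphabetical within
#'   a pair) and `split_age` (relative node height in `[0, 1]`), sorted by
#'   increasing `split_age`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' extract_sister_pairs(tr)
#' @export
extract_sister_pairs <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  h <- node_heights(tree)
  n <- ape::Ntip(tree)
  internal <- unique(tree$edge[, 1L])
  out <- list()
  for (v in internal) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    tipkids <- kids[kids <= n]
    if (length(kids) == 2L && length(tipkids) == 2L) {
      lab <- sort(tree$tip.label[tipkids])
      out[[length(out) + 1L]] <- data.frame(
        tip_a = lab[1L], tip_b = lab[2L],
        split_age = h$relative[v], stringsAsFactors = FALSE)
    } else if (length(kids) >= 3L && length(tipkids) == length(kids)) {
      warning("polytomy of ", length(kids),
              " tips at node ", v, " skipped in sister-pair extraction")
    }
  }
  if (length(out) == 0L)
    return(data.frame(tip_a = character(), tip_b = character(),
                      split_age = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$split_age, res$tip_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a sister-pair table as TSV
#'
#' @param pairs data frame from [extract_sister_pairs()] or
#'   [classify_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
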