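#' Parse a single newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Bracketed comments are
#' stripped, quoted labels are allowed, and structural problems (unbalanced
#' parentheses, duplicate or empty tip labels, empty input) raise errors that
#' name the offending position or label. Branch lengths are optional at parse
#' time; likelihood functions check for them separately, while parsimony
#' ignores them.
#'
#' @param text A newick string, terminated by `;`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop_binasr("empty newick input", class = "binasr_parse_error")
  }
  txt <- gsub("\\[[^]]*\\]", "", text) # strip comments
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop_binasr("unbalanced parenthesis at position ", i,
        class = "binasr_parse_error"
      )
    }
  }
  if (depth != 0L) {
    stop_binasr("unbalanced parentheses: ", depth, " unclosed '(' at end of input",
      class = "binasr_parse_error"
    )
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !is_phylo(tree)) {
    stop_binasr("could not parse newick string", class = "binasr_parse_error")
  }
  validate_tree(tree)
}

validate_tree <- function(tree) {
  tree$tip.label <- trimws(gsub("^'(.*)'$", "\\1", tree$tip.label))
  if (any(!nzchar(tree$tip.label))) {
    stop_binasr("empty tip label", class = "binasr_parse_error")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop_binasr("duplicate tip labels: ", paste(dup, collapse = ", "),
      class = "binasr_parse_error"
    )
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop_binasr("negative branch length", class = "binasr_parse_error")
  }
  tree
}

#' Write trees as newick text
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param path Optional file path; when `NULL` the newick strings are
#'   returned invisibly only.
#' @return (Invisibly) the newick string(s).
#' @export
write_newick <- function(trees, path = NULL) {
  txt <- ape::write.tree(trees, digits = 12)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Read a sample of trees sharing one tip-label universe
#'
#' Reads either a file of one newick tree per line or a NEXUS trees block
#' (translate tables are resolved by [ape::read.nexus()]). All trees must
#' share the same tip-label set; a mismatch raises an error listing the
#' symmetric difference.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (sniff for `#NEXUS`), `"newick"` or `"nexus"`.
#' @param quiet Suppress the tree-count message.
#' @return A `multiPhylo` object in file order.
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus"),
                             quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_binasr("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
      "nexus"
    } else {
      "newick"
    }
  }
  trees <- if (format == "nexus") {
    ape::read.nexus(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop_binasr("no trees in file: ", path)
    tl <- lapply(lines, parse_newick)
    structure(tl, class = "multiPhylo")
  }
  trees <- as_multiphylo(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(lab, ref)) {
      diff <- c(setdiff(lab, ref), setdiff(ref, lab))
      stop_binasr(
        "tree ", i, " has a different tip set; symmetric difference: ",
        paste(diff, collapse = ", ")
      )
    }
  }
  if (!quiet) message("read ", length(trees), " trees from ", path)
  trees
}

#' Construct or validate a tip-state table
#'
#' A tip-state table is a tibble with columns `taxon` (unique, non-empty
#' character) and `state` (integer 0, 1 or `NA`). State semantics are fixed:
#' 0 = unicellular, 1 = multicellular, `NA` = missing.
#'
#' @param x A data frame with columns `taxon` and `state`, or a named
#'   vector of 0/1/NA.
#' @return A validated `tip_states` tibble.
#' @export
as_tip_states <- function(x) {
  if (inherits(x, "tip_states")) return(x)
  if (is.atomic(x) && !is.null(names(x))) {
    x <- tibble::tibble(taxon = names(x), state = as.integer(x))
  }
  if (!is.data.frame(x) || !all(c("taxon", "state") %in% names(x))) {
    stop_binasr("tip states must have columns 'taxon' and 'state'")
  }
  tab <- tibble::as_tibble(x[, c("taxon", "state")])
  tab$taxon <- trimws(as.character(tab$taxon))
  tab$state <- as.integer(tab$state)
  if (any(!nzchar(tab$taxon))) stop_binasr("empty taxon label in state table")
  dup <- unique(tab$taxon[duplicated(tab$taxon)])
  if (length(dup)) {
    stop_binasr("duplicate taxon labels: ", paste(dup, collapse = ", "))
  }
  bad <- !is.na(tab$state) & !(tab$state %in% c(0L, 1L))
  if (any(bad)) {
    stop_binasr(
      "states must be 0, 1 or missing; offending taxa: ",
      paste(tab$taxon[bad], collapse = ", ")
    )
  }
  class(tab) <- c("tip_states", class(tab))
  tab
}

#' Read a two-column tab-separated tip-state table
#'
#' Lines starting with `#` are skipped. Recognized state tokens are
#' configurable; the defaults map `0`/`unicellular` to 0, `1`/`multicellular`
#' to 1 and `?`/`-` to missing. Unknown tokens and duplicate labels raise an
#' error naming the line.
#'
#' @param path Path to the TSV file.
#' @param tokens0,tokens1,tokens_na Character vectors of accepted tokens.
#' @param quiet Suppress the composition message.
#' @return A `tip_states` tibble.
#' @export
read_states <- function(path,
                        tokens0 = c("0", "unicellular"),
                        tokens1 = c("1", "multicellular"),
                        tokens_na = c("?", "-"),
                        quiet = FALSE) {
  if (!file.exists(path)) stop_binasr("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_binasr("no data rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- character(length(parts))
  states <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (length(p) != 2L) {
      stop_binasr("line ", lineno[i], ": expected two tab-separated fields")
    }
    taxa[i] <- p[1]
    tok <- tolower(p[2])
    states[i] <- if (tok %in% tolower(tokens0)) {
      0L
    } else if (tok %in% tolower(tokens1)) {
      1L
    } else if (tok %in% tolower(tokens_na)) {
      NA_integer_
    } else {
      stop_binasr("line ", lineno[i], ": unknown state token '", p[2], "'")
    }
    if (taxa[i] %in% taxa[seq_len(i - 1L)]) {
      stop_binasr("line ", lineno[i], ": duplicate taxon label '", taxa[i], "'")
    }
  }
  tab <- as_tip_states(tibble::tibble(taxon = taxa, state = states))
  if (!quiet) {
    message(
      "read ", nrow(tab), " taxa: ", sum(tab$state == 0, na.rm = TRUE),
      " state 0, ", sum(tab$state == 1, na.rm = TRUE), " state 1, ",
      sum(is.na(tab$state)), " missing"
    )
  }
  tab
}

#' Write a tip-state table as two-column TSV
#'
#' @param states A tip-state table (see [as_tip_states()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_states <- function(states, path) {
  tab <- as_tip_states(states)
  tok <- ifelse(is.na(tab$state), "?", as.character(tab$state))
  writeLines(paste(tab$taxon, tok, sep = "\t"), path)
  invisible(path)
}

#' Remove tips from a tree
#'
#' Drops the listed tips and suppresses the resulting unary nodes, summing
#' their branch lengths (via [ape::drop.tip()]). The typical use is removing
#' an outgroup so its state cannot bias ingroup reconstructions.
#'
#' @param tree A `phylo` object.
#' @param labels Tip labels to remove; must all be present, and at least two
#'   tips must remain.
#' @return The pruned `phylo` object.
#' @export
prune_taxa <- function(tree, labels) {
  if (!is_phylo(tree)) stop_binasr("expected a 'phylo' object")
  labels <- unique(as.character(labels))
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    stop_binasr("unknown tip labels: ", paste(unknown, collapse = ", "))
  }
  if (ape::Ntip(tree) - length(labels) < 2L) {
    stop_binasr("pruning would leave fewer than 2 tips")
  }
  ape::drop.tip(tree, labels, collapse.singles = TRUE)
}

#' Bundled cyanobacterial tip-state table
#'
#' The 58-taxon unicellular/multicellular coding used throughout the
#' package's examples: 22 single-celled taxa from morphological section I and
#' 7 from section II (state 0), 21 multicellular taxa from section III, 5
#' from section IV and 3 from section V (state 1) — a 29:29 ratio. The
#' outgroup (*Beggiatoa sp.* 'Chiprana') is intentionally not part of the
#' table; its state is excluded from all analyses.
#'
#' @return A `tip_states` tibble with 58 rows.
#' @export
cyano_states <- function() {
  read_states(
    system.file("extdata", "cyano_states.tsv", package = "binasr"),
    quiet = TRUE
  )
}

#' Named clade membership lists for the bundled dataset
#'
#' Partial tip membership of the three deep clades (E, AC and C) whose
#' ancestors carry the multicellularity signal. Only taxa whose clade
#' membership is stated explicitly in the source study's text are listed, so
#' the lists are partial and intended for `mrca`-mode node queries, where a
#' subset of a clade's tips identifies the same ancestor.
#'
#' @return A tibble with columns `clade` and `taxon`.
#' @export
cyano_clades <- function() {
  path <- system.file("extdata", "cyano_clades.tsv", package = "binasr")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    clade = vapply(parts, `[`, character(1), 1L),
    taxon = vapply(parts, `[`, character(1), 2L)
  )
}
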