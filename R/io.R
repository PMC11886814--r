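#' Read a nucleotide alignment
#'
#' Reads a multiple sequence alignment from FASTA (multi-line sequences
#' allowed) or relaxed sequential PHYLIP (first line \code{ntax nchar},
#' whitespace-separated names, sequences may wrap over lines).  Characters
#' are normalized to upper case; the alphabet is A, C, G, T plus the missing
#' and ambiguity set (\code{- ? N X .} and the IUPAC ambiguity codes, which
#' the pipeline treats as missing).
#'
#' @param path input file.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @return character matrix, one row per taxon (rownames are taxon labels),
#'   one column per aligned site.
#' @export
readAlignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- switch(format,
                 fasta = .readFasta(path),
                 phylip = .readPhylipRelaxed(path))
  .alignmentFromSequences(seqs)
}

.readFasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  grp <- cumsum(hdr)
  nms <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(seqs, nms)
}

.readPhylipRelaxed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("relaxed PHYLIP must start with 'ntax nchar'")
  ntax <- dims[1]; nchar_ <- dims[2]
  body <- lines[-1]
  seqs <- character(0); cur_name <- NULL; cur <- ""
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (is.null(cur_name) || nchar(gsub("\\s", "", cur)) >= nchar_) {
      if (!is.null(cur_name)) seqs[cur_name] <- cur
      cur_name <- toks[1]
      cur <- paste(toks[-1], collapse = "")
    } else {
      cur <- paste0(cur, paste(toks, collapse = ""))
    }
  }
  if (!is.null(cur_name)) seqs[cur_name] <- cur
  if (length(seqs) != ntax)
    stop("expected ", ntax, " sequences, found ", length(seqs))
  seqs
}

.alignmentFromSequences <- function(seqs) {
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms))) stop("unnamed sequence in input")
  if (anyDuplicated(nms))
    stop("duplicate taxon label: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- nms[lens != lens[1]][1]
    stop("unequal sequence lengths (offending taxon: ", bad, ")")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- nms
  ok <- mat %in% c(NUC_STATES, MISSING_STATES)
  if (!all(ok)) {
    pos <- which(!matrix(ok, nrow = nrow(mat)), arr.ind = TRUE)[1, ]
    stop("unknown character '", mat[pos[1], pos[2]], "' in taxon ",
         nms[pos[1]], " at column ", pos[2])
  }
  mat
}

#' Write an alignment as FASTA
#'
#' @param aln character matrix as returned by [readAlignment()] or
#'   [simulateAlignment()].
#' @param path output file.
#' @param width line width for wrapping sequences.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(aln, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", rownames(aln)[i]), chunks), con)
  }
  invisible(path)
}

#' Read clade definitions
#'
#' Parses a tab-separated clade-definition file with one clade per line:
#' \code{code<TAB>role<TAB>comma-separated taxon labels}, where role is
#' \code{ingroup} or \code{outgroup}.  Exactly one outgroup line is
#' required.  Alignment taxa not assigned to any clade are reported with a
#' warning and ignored.
#'
#' @param path clade-definition file.
#' @param alignment alignment matrix the definitions refer to.
#' @return a validated \linkS4class{CladeMap}.
#' @export
readCladeMap <- function(path, alignment) {
  if (!file.exists(path)) stop("clade file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  clades <- list(); roles <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("malformed clade line (need code<TAB>role<TAB>taxa): ", ln)
    code <- trimws(f[1]); role <- tolower(trimws(f[2]))
    taxa <- if (length(f) >= 3L)
      trimws(strsplit(f[3], ",", fixed = TRUE)[[1]]) else character(0)
    taxa <- taxa[nzchar(taxa)]
    if (!role %in% c("ingroup", "outgroup"))
      stop("unknown clade role '", role, "' for clade ", code)
    if (length(taxa) == 0L) stop("clade ", code, " has no taxa")
    if (code %in% names(clades)) stop("duplicate clade code: ", code)
    clades[[code]] <- taxa
    roles[code] <- role
  }
  if (sum(roles == "outgroup") != 1L)
    stop("exactly one outgroup clade is required")
  all_taxa <- unlist(clades, use.names = FALSE)
  missing <- setdiff(all_taxa, rownames(alignment))
  if (length(missing))
    stop("clade taxa absent from alignment: ",
         paste(missing, collapse = ", "))
  unassigned <- setdiff(rownames(alignment), all_taxa)
  if (length(unassigned))
    warning(length(unassigned), " alignment taxa not assigned to any ",
            "clade are ignored: ", paste(unassigned, collapse = ", "))
  cladeMap(clades, names(roles)[roles == "outgroup"])
}

# ---- rooted clade trees / Newick ------------------------------------------

.canonicalNode <- function(node) {
  if (is.character(node)) return(node)
  children <- lapply(node, .canonicalNode)
  keys <- vapply(children, function(ch) min(.treeTips(ch)), character(1))
  children[order(keys)]
}

.nodeToNewick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, .nodeToNewick, character(1)),
                    collapse = ","), ")")
}

.rootedCladeTree <- function(node) {
  node <- .canonicalNode(node)
  new("RootedCladeTree", node = node, tips = sort(.treeTips(node)))
}

#' Parse and write rooted clade trees in Newick format
#'
#' \code{parseNewick} parses a Newick string (or single-tree file) into a
#' canonical \linkS4class{RootedCladeTree}; branch lengths and support
#' labels are ignored for clade trees.  \code{writeNewick} emits the
#' canonical Newick string, in which the children of every node are ordered
#' by their smallest leaf label, so \code{parseNewick(writeNewick(t))}
#' reproduces \code{t} exactly.
#'
#' @param text Newick string (terminated by \code{;}) or path to a file
#'   containing one.
#' @param leaves optional character vector; if given, the leaf set must
#'   equal it exactly.
#' @return \code{parseNewick}: a \code{RootedCladeTree};
#'   \code{writeNewick}: a character scalar ending in \code{";"}.
#' @examples
#' writeNewick(parseNewick("((D,C),(S,P));"))  # "((C,D),(P,S));"
#' @export
parseNewick <- function(text, leaves = NULL) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) NULL)
  if (!inherits(phy, "phylo")) stop("malformed Newick: ", text)
  node <- .phyloToNode(phy)
  tr <- .rootedCladeTree(node)
  if (!is.null(leaves) && !identical(tr@tips, sort(leaves)))
    stop("leaf set {", paste(tr@tips, collapse = ","),
         "} does not match expected {", paste(sort(leaves), collapse = ","),
         "}")
  validObject(tr)
  tr
}

.phyloToNode <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(n) {
    if (n <= ntip) return(phy$tip.label[n])
    lapply(kids[[as.character(n)]], build)
  }
  if (ntip == 1L) return(phy$tip.label)
  build(ntip + 1L)
}

#' @rdname parseNewick
#' @param tree a \code{RootedCladeTree}.
#' @export
writeNewick <- function(tree) {
  stopifnot(is(tree, "RootedCladeTree"))
  paste0(.nodeToNewick(tree@node), ";")
}
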