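# SMILES export and import for substituted biphenyls.

.branchSmiles <- function(kind) {
  switch(kind, chlorine = "(Cl)", hydroxy = "(O)", methoxy = "(OC)", "")
}

#' @describeIn toSmiles Canonical SMILES of a substituted biphenyl.  With
#'   \code{asMethylEther = TRUE} every oxygen substituent is rendered as a
#'   methyl ether (the derivatized form actually injected on the GC);
#'   otherwise each substituent keeps its stored kind.  The string is
#'   built deterministically from the canonical orientation, so equal
#'   structures always yield byte-identical SMILES.
#' @export
setMethod("toSmiles", "BiphenylStructure",
          function(x, asMethylEther = FALSE) {
  kinds <- rep("", 10L)
  kinds[x@chlorines] <- "chlorine"
  sk <- x@substKind
  if (asMethylEther) sk[sk == "hydroxy"] <- "methoxy"
  kinds[x@substPos] <- sk
  branches <- vapply(kinds, .branchSmiles, character(1))
  # ring A: written so its last atom is the ipso carbon, which then bonds
  # to the first (ipso) atom of ring B
  ringA <- paste0("c1", branches[1], "c", branches[2], "c", branches[3],
                  "c", branches[4], "c", branches[5], "c1")
  ringB <- paste0("c2c", branches[6], "c", branches[7], "c", branches[8],
                  "c", branches[9], "c2", branches[10])
  paste0(ringA, "-", ringB)
})

# ---- SMILES import (OpenBabel-backed) ------------------------------------

# Convert SMILES strings to a list of molecular graphs via ChemmineOB.
# Returns, per molecule: elements (character), bonds (two-column integer
# matrix), order (integer bond orders), implicitH (integer per atom).
.molGraphsFromSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  smi <- paste0(paste(smiles, paste0("m", seq_along(smiles))),
                collapse = "\n")
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
  nMol <- length(gregexpr("$$$$", sdfstr, fixed = TRUE)[[1]])
  if (!nzchar(trimws(sdfstr)) || nMol != length(smiles)) {
    # find and name the offending input
    for (s in smiles) {
      one <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF",
                                                paste0(s, " x\n")),
                      error = function(e) "")
      if (!nzchar(trimws(one)))
        stop("unparseable SMILES input: '", s, "'")
    }
    stop("SMILES conversion failed for at least one input")
  }
  sdf <- ChemmineR::read.SDFset(
    ChemmineR::read.SDFstr(strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))
  if (length(sdf) != length(smiles))
    stop("SMILES conversion failed for at least one input: ",
         paste(utils::head(smiles, 3), collapse = " ; "))
  lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    order <- as.integer(bb[, 3])
    valence <- c(C = 4L, O = 2L, Cl = 1L, H = 1L)
    if (!all(elements %in% names(valence)))
      stop("unsupported element in '", smiles[i], "': ",
           paste(setdiff(elements, names(valence)), collapse = ", "))
    bsum <- integer(length(elements))
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds[k, 1]] <- bsum[bonds[k, 1]] + order[k]
      bsum[bonds[k, 2]] <- bsum[bonds[k, 2]] + order[k]
    }
    implicitH <- valence[elements] - bsum
    if (any(implicitH < 0L))
      stop("inconsistent valence while parsing '", smiles[i], "'")
    list(elements = elements, bonds = bonds, order = order,
         implicitH = as.integer(implicitH), smiles = smiles[i])
  })
}

#' Parse a biphenyl SMILES back into a structure record
#'
#' Recognizes the chlorinated/oxygenated biphenyl scaffold in an arbitrary
#' (not necessarily package-generated) SMILES string and returns the
#' corresponding canonical \code{\linkS4class{BiphenylStructure}}.
#' Methoxy groups are stored as kind \code{"methoxy"}, phenolic hydroxyls
#' as \code{"hydroxy"}.
#'
#' @param smiles a single SMILES string.
#' @return a \code{\linkS4class{BiphenylStructure}}.
#' @examples
#' \donttest{
#' s <- parseBiphenylSmiles("Clc1ccc(cc1)-c1ccccc1")
#' canonicalName(s)  # "PCB 3"
#' }
#' @export
parseBiphenylSmiles <- function(smiles) {
  g <- .molGraphsFromSmiles(smiles)[[1]]
  el <- g$elements
  gr <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
  if (igraph::vcount(gr) < length(el))
    gr <- igraph::add_vertices(gr, length(el) - igraph::vcount(gr))
  core <- igraph::coreness(gr)
  ring <- which(core >= 2L)
  if (length(ring) != 12L || !all(el[ring] == "C"))
    stop("not a biphenyl scaffold: '", smiles, "'")
  sub <- igraph::induced_subgraph(gr, ring, impl = "copy_and_delete")
  bridges <- igraph::bridges(sub)
  if (length(bridges) != 1L)
    stop("not a biphenyl scaffold (no unique inter-ring bond): '",
         smiles, "'")
  ends <- igraph::ends(sub, bridges[[1]])
  ipsoA <- ring[ends[1]]; ipsoB <- ring[ends[2]]
  sub2 <- igraph::delete_edges(sub, bridges[[1]])
  comp <- igraph::components(sub2)$membership
  ringOf <- function(ipso) ring[comp == comp[match(ipso, ring)]]

  walkRing <- function(ipso, ringAtoms) {
    # order the five substitutable carbons 2..6 starting at one ipso
    # neighbour; the direction choice is absorbed by canonicalization
    adj <- function(v) intersect(as.integer(igraph::neighbors(gr, v)),
                                 ringAtoms)
    nb <- adj(ipso)
    path <- c(ipso, nb[1])
    while (length(path) < 6L) {
      nxt <- setdiff(adj(path[length(path)]), path)
      path <- c(path, nxt[1])
    }
    path[-1]  # positions 2..6
  }

  substAt <- function(atom) {
    out <- setdiff(as.integer(igraph::neighbors(gr, atom)), ring)
    if (length(out) == 0L) return("")
    if (length(out) > 1L)
      stop("unsupported substitution at a ring carbon in '", smiles, "'")
    if (el[out] == "Cl") return("chlorine")
    if (el[out] == "O") {
      beyond <- setdiff(as.integer(igraph::neighbors(gr, out)), atom)
      if (length(beyond) == 0L) return("hydroxy")
      if (length(beyond) == 1L && el[beyond] == "C") return("methoxy")
    }
    stop("unsupported substituent in '", smiles, "'")
  }

  slots <- c(walkRing(ipsoA, ringOf(ipsoA)), walkRing(ipsoB, ringOf(ipsoB)))
  kinds <- vapply(slots, substAt, character(1))
  clSlots <- which(kinds == "chlorine")
  sSlots <- which(kinds %in% c("hydroxy", "methoxy"))
  subst <- structure(kinds[sSlots], names = .POS_LABELS[sSlots])
  biphenylStructure(.POS_LABELS[clSlots], subst)
}

#' Write structures as a SMILES TSV
#'
#' One line per structure: name column then SMILES, the exchange format of
#' the enumeration interface.
#'
#' @param structures list of \code{\linkS4class{BiphenylStructure}}.
#' @param file output path.
#' @param asMethylEther write the methylated derivatives.
#' @export
writeSmilesTable <- function(structures, file, asMethylEther = FALSE) {
  df <- data.frame(
    name = vapply(structures, canonicalName, character(1)),
    smiles = vapply(structures, toSmiles, character(1),
                    asMethylEther = asMethylEther),
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
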