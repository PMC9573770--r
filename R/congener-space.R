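# Enumeration of the PCB congener space and its hydroxylated derivatives.

.ohpcbCache <- new.env(parent = emptyenv())

# The strict ordering rule (homolog size, then locant sequence) reproduces
# the accepted Ballschmiter-Zell list except for the historical numbering
# irregularity at PCB 107-109, fixed up by this permutation:
# strict rank 107 (2,3,3',4,5') is PCB 108, 108 (2,3,3',4,6) is PCB 109,
# and 109 (2,3,3',4',5) is PCB 107.
.BZ_FIXUP <- c("107" = 108L, "108" = 109L, "109" = 107L)

.bzTable <- function() {
  if (!is.null(.ohpcbCache$bz)) return(.ohpcbCache$bz)
  pats <- vector("list", 1024L)
  n <- 0L
  for (k in 1:10) {
    cmb <- utils::combn(10L, k)
    seen <- new.env(parent = emptyenv())
    for (j in seq_len(ncol(cmb))) {
      cp <- .canonChlorineSlots(cmb[, j])
      key <- paste(cp, collapse = "-")
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        n <- n + 1L
        pats[[n]] <- cp
      }
    }
  }
  pats <- pats[seq_len(n)]
  nCl <- vapply(pats, length, integer(1))
  keys <- vapply(pats, .slotSeqKey, character(1))
  strict <- pats[order(nCl, keys)]
  official <- strict
  for (from in names(.BZ_FIXUP)) {
    official[[.BZ_FIXUP[[from]]]] <- strict[[as.integer(from)]]
  }
  lookup <- structure(seq_along(official),
                      names = vapply(official, paste, character(1),
                                     collapse = "-"))
  .ohpcbCache$bz <- list(patterns = official, lookup = lookup)
  .ohpcbCache$bz
}

#' Enumerate all 209 PCB congeners
#'
#' Generates every symmetry-distinct chlorinated biphenyl with one to ten
#' chlorines, ordered and numbered by the Ballschmiter-Zell (BZ)
#' convention.  Symmetry means ring exchange and 180-degree rotation of
#' either ring about the inter-ring bond, the physical indistinguishability
#' of the biphenyl numbering.
#'
#' @return list of 209 \code{\linkS4class{BiphenylStructure}} congeners in
#'   BZ order, named \code{"PCB 1"} .. \code{"PCB 209"}.
#' @examples
#' length(enumeratePcbCongeners())  # 209
#' @export
enumeratePcbCongeners <- function() {
  tab <- .bzTable()
  out <- lapply(tab$patterns, function(p)
    new("BiphenylStructure", chlorines = p, substPos = integer(0),
        substKind = character(0)))
  names(out) <- paste("PCB", seq_along(out))
  out
}

#' Look up a congener by its BZ number
#'
#' @param bz integer in 1..209.
#' @return the congener as a \code{\linkS4class{BiphenylStructure}}.
#' @examples
#' chlorinePositions(congenerFromBz(95))  # 2, 2', 3, 5', 6
#' @export
congenerFromBz <- function(bz) {
  bz <- as.integer(bz)
  if (length(bz) != 1L || is.na(bz) || bz < 1L || bz > 209L)
    stop("BZ number must be a single integer in 1..209")
  tab <- .bzTable()
  new("BiphenylStructure", chlorines = tab$patterns[[bz]],
      substPos = integer(0), substKind = character(0))
}

#' @describeIn bzNumber BZ number of the chlorination pattern of a
#'   structure (substituents ignored).
#' @export
setMethod("bzNumber", "BiphenylStructure", function(x) {
  cp <- .canonChlorineSlots(x@chlorines)
  if (length(cp) == 0L) return(NA_integer_)
  tab <- .bzTable()
  unname(tab$lookup[[paste(cp, collapse = "-")]])
})

#' Enumerate all 837 mono-hydroxylated PCBs
#'
#' Every symmetry-distinct structure carrying one hydroxy group and one to
#' nine chlorines on the remaining positions: the complete mono-OH
#' derivative space of the 209 PCB congeners, chlorine count preserved.
#'
#' @return list of 837 \code{\linkS4class{BiphenylStructure}} objects,
#'   ordered by parent BZ number then hydroxy locant.
#' @examples
#' length(enumerateMonoOhPcbs())  # 837
#' @export
enumerateMonoOhPcbs <- function() {
  if (!is.null(.ohpcbCache$monoOh)) return(.ohpcbCache$monoOh)
  out <- list()
  seen <- new.env(parent = emptyenv())
  congeners <- enumeratePcbCongeners()
  for (bz in seq_along(congeners)) {
    cl <- congeners[[bz]]@chlorines
    if (length(cl) == 10L) next
    free <- setdiff(1:10, cl)
    free <- free[order(.POS_SORTKEY[free])]
    for (pos in free) {
      can <- .canonStructureSlots(cl, pos, "hydroxy")
      key <- .structureKey(can$chlorines, can$substPos, can$substKind)
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <-
          new("BiphenylStructure", chlorines = can$chlorines,
              substPos = can$substPos, substKind = can$substKind)
      }
    }
  }
  names(out) <- vapply(out, canonicalName, character(1))
  .ohpcbCache$monoOh <- out
  out
}

#' Generate metabolite candidate structures for a parent congener
#'
#' Builds the hydroxylated metabolite candidate space of a PCB congener
#' from up to three structural classes:
#' \describe{
#'   \item{\code{direct}}{hydroxy insertion at each chlorine-free ring
#'     position (chlorine count preserved, congener number unchanged).}
#'   \item{\code{shift_1_2}}{NIH 1,2-shift products: one chlorine migrates
#'     to an adjacent free position on the same ring and the hydroxy group
#'     takes the vacated position, so the congener number changes (e.g.
#'     3-103 from PCB 95, 4-22 and 4'-25 from PCB 28).}
#'   \item{\code{di_oh}}{dihydroxylated metabolites with the two hydroxy
#'     groups ortho (catechol) or para (hydroquinone-like) to each other on
#'     free positions of one ring; set \code{fullDiOh = TRUE} to enumerate
#'     all free position pairs instead.}
#' }
#' Members are deduplicated under the biphenyl numbering symmetry; the
#' first-listed class wins when two classes yield the same structure.
#'
#' @param parent a PCB congener (\code{\linkS4class{BiphenylStructure}}
#'   without substituents) or a BZ number.
#' @param classes subset of \code{c("direct", "shift_1_2", "di_oh")}.
#' @param fullDiOh enumerate every free di-hydroxylation pair, not only
#'   ortho/para-related ones.
#' @return a \code{\linkS4class{CandidateSet}}.
#' @examples
#' cs <- generateMetaboliteCandidates(95, classes = "shift_1_2")
#' vapply(candidateMembers(cs), canonicalName, character(1))
#' @export
generateMetaboliteCandidates <- function(parent,
                                         classes = c("direct", "shift_1_2",
                                                     "di_oh"),
                                         fullDiOh = FALSE) {
  if (is.numeric(parent)) parent <- congenerFromBz(parent)
  stopifnot(is(parent, "BiphenylStructure"))
  if (length(parent@substPos))
    stop("'parent' must be a plain congener without substituents")
  classes <- as.character(classes)
  if (length(classes) == 0L)
    stop("at least one candidate class must be requested")
  bad <- setdiff(classes, c("direct", "shift_1_2", "di_oh"))
  if (length(bad))
    stop("unknown candidate class(es): ", paste(bad, collapse = ", "))

  cl <- parent@chlorines
  free <- setdiff(1:10, cl)
  members <- list(); prov <- character(0)
  seen <- new.env(parent = emptyenv())
  addMember <- function(chlorines, substPos, class) {
    kind <- rep("hydroxy", length(substPos))
    can <- .canonStructureSlots(chlorines, substPos, kind)
    key <- .structureKey(can$chlorines, can$substPos, can$substKind)
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      members[[length(members) + 1L]] <<-
        new("BiphenylStructure", chlorines = can$chlorines,
            substPos = can$substPos, substKind = can$substKind)
      prov <<- c(prov, class)
    }
  }

  for (class in intersect(c("direct", "shift_1_2", "di_oh"), classes)) {
    if (class == "direct") {
      for (pos in free) addMember(cl, pos, "direct")
    } else if (class == "shift_1_2") {
      for (c0 in cl) {
        for (tgt in intersect(.adjacentSlots(c0), free)) {
          addMember(c(setdiff(cl, c0), tgt), c0, "shift_1_2")
        }
      }
    } else {
      if (length(free) >= 2L) {
        prs <- utils::combn(free, 2L)
        for (j in seq_len(ncol(prs))) {
          a <- prs[1L, j]; b <- prs[2L, j]
          related <- b %in% .adjacentSlots(a) ||
            identical(.paraSlot(a), b)
          if (fullDiOh || related) addMember(cl, c(a, b), "di_oh")
        }
      }
    }
  }
  new("CandidateSet", parent = parent, members = members, provenance = prov)
}

#' @describeIn CandidateSet-class list of member structures
#' @param x a \code{CandidateSet}.
#' @export
candidateMembers <- function(x) x@members

#' @describeIn CandidateSet-class provenance class per member
#' @export
candidateProvenance <- function(x) x@provenance

#' @describeIn CandidateSet-class parent congener
#' @export
candidateParent <- function(x) x@parent

#' @export
setMethod("length", "CandidateSet", function(x) length(x@members))

# ---- accessors -----------------------------------------------------------

#' @describeIn chlorineCount number of chlorines
#' @export
setMethod("chlorineCount", "BiphenylStructure",
          function(x) length(x@chlorines))

#' @describeIn chlorinePositions chlorine position labels
#' @export
setMethod("chlorinePositions", "BiphenylStructure", function(x)
  .posLabels(x@chlorines)[order(.POS_SORTKEY[x@chlorines])])

#' @describeIn substituentCount number of oxygen substituents
#' @export
setMethod("substituentCount", "BiphenylStructure",
          function(x) length(x@substPos))

#' @describeIn substituentPositions substituent position labels
#' @export
setMethod("substituentPositions", "BiphenylStructure",
          function(x) .posLabels(x@substPos))

#' @describeIn substituentKinds substituent kinds
#' @export
setMethod("substituentKinds", "BiphenylStructure",
          function(x) x@substKind)

#' @describeIn positionClasses ortho/meta/para class of each substituent
#'   position
#' @export
setMethod("positionClasses", "BiphenylStructure",
          function(x) .POS_CLASS[x@substPos])

#' @describeIn canonicalName Field-standard short name: substituent
#'   locants plus the BZ number of the chlorination pattern, e.g.
#'   \code{"4'-95"} for the 4'-OH metabolite of PCB 95, or
#'   \code{"PCB 28"} for a plain congener.
#' @export
setMethod("canonicalName", "BiphenylStructure", function(x) {
  bz <- bzNumber(x)
  if (length(x@substPos) == 0L) {
    if (is.na(bz)) return("biphenyl")
    return(paste("PCB", bz))
  }
  pos <- .posLabels(x@substPos)[order(.POS_SORTKEY[x@substPos])]
  paste0(paste(pos, collapse = ","), "-", if (is.na(bz)) 0L else bz)
})

#' Parse a canonical metabolite name
#'
#' Inverse of \code{\link{canonicalName}}: \code{"4'-95"} gives the
#' structure with the PCB 95 chlorination pattern and a substituent at
#' position 4'.  Typographic primes and dashes are accepted.
#'
#' @param name name string like \code{"3-103"}, \code{"4,5-95"} or
#'   \code{"PCB 28"}.
#' @param kind substituent kind to assign, \code{"hydroxy"} (default) or
#'   \code{"methoxy"}.
#' @return a \code{\linkS4class{BiphenylStructure}}.
#' @export
parseCanonicalName <- function(name, kind = "hydroxy") {
  name <- gsub("′", "'", gsub("–|—", "-", trimws(name)))
  if (grepl("^PCB +[0-9]+$", name)) {
    return(congenerFromBz(as.integer(sub("^PCB +", "", name))))
  }
  m <- regmatches(name, regexec("^([0-9',]+)-([0-9]+)$", name))[[1]]
  if (length(m) != 3L)
    stop("cannot parse metabolite name: '", name, "'")
  pos <- strsplit(m[2], ",", fixed = TRUE)[[1]]
  parent <- congenerFromBz(as.integer(m[3]))
  subst <- structure(rep(kind, length(pos)), names = pos)
  biphenylStructure(chlorinePositions(parent), subst)
}

# ---- show methods --------------------------------------------------------

setMethod("show", "BiphenylStructure", function(object) {
  nm <- canonicalName(object)
  kinds <- if (length(object@substKind))
    paste0(" [", paste(object@substKind, collapse = ", "), "]") else ""
  cat("BiphenylStructure: ", nm, kinds, "\n", sep = "")
  cat("  chlorines: ",
      if (length(object@chlorines))
        paste(chlorinePositions(object), collapse = ", ") else "none",
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet for", canonicalName(object@parent), "with",
      length(object@members), "members\n")
  tab <- table(object@provenance)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(object)
})

#' Export a candidate set as a data.frame
#'
#' One row per member: name, SMILES (as methyl ether and free phenol),
#' provenance class and parent BZ number; the CSV dialect of the
#' candidate-set interface.
#'
#' @param x a \code{\linkS4class{CandidateSet}}.
#' @param file optional path; when given the table is written as CSV.
#' @return the data.frame, invisibly when \code{file} is given.
#' @export
candidateTable <- function(x, file = NULL) {
  stopifnot(is(x, "CandidateSet"))
  df <- data.frame(
    name = vapply(x@members, canonicalName, character(1)),
    smiles = vapply(x@members, toSmiles, character(1),
                    asMethylEther = TRUE),
    provenance = x@provenance,
    parent_bz = rep(bzNumber(x@parent), length(x@members)),
    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
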