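# Ring-position bookkeeping for the biphenyl scaffold.
#
# The ten substitutable positions are indexed by slot codes 1..10 in the
# order 2,3,4,5,6 (unprimed ring) then 2',3',4',5',6' (primed ring).
# Positions 1 and 1' are the ipso carbons of the inter-ring bond and are
# never substituted.

.POS_LABELS <- c("2", "3", "4", "5", "6", "2'", "3'", "4'", "5'", "6'")

# Locant ordering 2 < 2' < 3 < 3' < 4 < 4' < 5 < 5' < 6 < 6' used by the
# Ballschmiter-Zell convention, encoded as integer sort keys per slot.
.POS_SORTKEY <- c(4L, 6L, 8L, 10L, 12L, 5L, 7L, 9L, 11L, 13L)

# Symmetry group of the numbering (order 8): identity, 180-degree rotation
# of either ring about the inter-ring axis (2<->6, 3<->5), and ring
# exchange, plus compositions.  Each element is a permutation p such that
# the content of slot i moves to slot p[i].
.FLIP_A <- c(5L, 4L, 3L, 2L, 1L, 6L, 7L, 8L, 9L, 10L)
.FLIP_B <- c(1L, 2L, 3L, 4L, 5L, 10L, 9L, 8L, 7L, 6L)
.SWAP <- c(6L, 7L, 8L, 9L, 10L, 1L, 2L, 3L, 4L, 5L)

.SYM_GROUP <- local({
  fa <- .FLIP_A; fb <- .FLIP_B; sw <- .SWAP
  comp <- function(p, q) p[q]  # apply q first, then p
  list(1:10, fa, fb, comp(fa, fb), sw, comp(sw, fa), comp(sw, fb),
       comp(sw, comp(fa, fb)))
})

# ortho = 2/6/2'/6', meta = 3/5/3'/5', para = 4/4'
.POS_CLASS <- c("ortho", "meta", "para", "meta", "ortho")[rep(1:5, 2)]

.slotRing <- function(slots) ifelse(slots <= 5L, "A", "B")

# neighbours among substitutable positions on the same ring (2-3-4-5-6 path;
# 2 and 6 are both adjacent to the ipso carbon, not to each other)
.adjacentSlots <- function(slot) {
  base <- if (slot <= 5L) 0L else 5L
  i <- slot - base
  nb <- c(i - 1L, i + 1L)
  nb <- nb[nb >= 1L & nb <= 5L]
  nb + base
}

# para partner within a ring (benzene para pairs among 2..6: 2-5 and 3-6)
.paraSlot <- function(slot) {
  base <- if (slot <= 5L) 0L else 5L
  i <- slot - base
  p <- c(4L, 5L, NA_integer_, 1L, 2L)[i]
  if (is.na(p)) NA_integer_ else p + base
}

.matchPositions <- function(labels) {
  labels <- gsub("′", "'", as.character(labels))
  codes <- match(labels, .POS_LABELS)
  if (anyNA(codes)) {
    stop("unknown ring position(s): ",
         paste(labels[is.na(codes)], collapse = ", "),
         " (valid: ", paste(.POS_LABELS, collapse = ", "), ")")
  }
  as.integer(codes)
}

.posLabels <- function(slots) .POS_LABELS[slots]

# fixed-width key string for lexicographic ordering of a slot set under
# the BZ locant order
.slotSeqKey <- function(slots) {
  if (length(slots) == 0L) return("")
  paste(sprintf("%02d", sort(.POS_SORTKEY[slots])), collapse = "")
}

.applySym <- function(slots, p) sort(p[slots])

# Canonical representative of a chlorination pattern: among the eight
# symmetry images, prefer the maximum chlorine count on the unprimed ring,
# then the lexicographically smallest locant sequence.  This reproduces
# the representatives used by the Ballschmiter-Zell congener list.
.canonChlorineSlots <- function(slots) {
  slots <- sort(as.integer(slots))
  if (length(slots) == 0L) return(integer(0))
  imgs <- lapply(.SYM_GROUP, function(p) .applySym(slots, p))
  nA <- vapply(imgs, function(s) sum(s <= 5L), integer(1))
  imgs <- imgs[nA == max(nA)]
  keys <- vapply(imgs, .slotSeqKey, character(1))
  imgs[[which.min(rank(keys, ties.method = "min"))]]
}

# Canonical representative of a full substituted structure.  The chlorine
# part is forced onto its BZ-canonical representative; among symmetry
# images achieving it, the substituent locant sequence (with kind as a
# tie-break) is minimized.  Returns list(chlorines, substPos, substKind).
.canonStructureSlots <- function(chlorines, substPos, substKind) {
  chlorines <- sort(as.integer(chlorines))
  substPos <- as.integer(substPos)
  clCanon <- .canonChlorineSlots(chlorines)
  best <- NULL
  bestKey <- NULL
  for (p in .SYM_GROUP) {
    clImg <- .applySym(chlorines, p)
    if (!identical(clImg, clCanon)) next
    sImg <- p[substPos]
    ord <- order(.POS_SORTKEY[sImg])
    key <- paste(sprintf("%02d%s", .POS_SORTKEY[sImg][ord],
                         substr(substKind[ord], 1, 1)), collapse = "")
    if (is.null(best) || key < bestKey) {
      best <- list(chlorines = clImg, substPos = sImg[ord],
                   substKind = substKind[ord])
      bestKey <- key
    }
  }
  best
}

.structureKey <- function(chlorines, substPos, substKind) {
  paste(paste(chlorines, collapse = ","),
        paste(substPos, collapse = ","),
        paste(substKind, collapse = ","), sep = "|")
}
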