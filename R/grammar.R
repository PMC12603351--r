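# Rearrangement grammar: tokenizer, parser, operation derivation.
#
# A rule "SRC→TGT" rewrites an ordered run of reference intervals. Capital
# letters are reference intervals, '_' a dispersion interval separating
# segments, lowercase marks inversion on the target side, '+' a variable
# copy number, and '()' on the source side marks the anchored sub-span used
# by placement constraints (empty '()' anchors a single breakend).

svError <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "svforgeError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

parseError <- function(msg) svError(msg, "svforgeParseError")

emptyTokenFrame <- function() {
  data.frame(symbol = character(0), letter = character(0),
             inverted = logical(0), dispersion = logical(0),
             plus = logical(0), anchor = logical(0), seg = integer(0),
             stringsAsFactors = FALSE)
}

tokenizeSide <- function(text, side = c("source", "target")) {
  side <- match.arg(side)
  chars <- strsplit(text, "")[[1]]
  tok <- list()
  nDisp <- 0L
  inAnchor <- FALSE
  sawAnchor <- FALSE
  anchorJunction <- NA_integer_
  anchorEmpty <- FALSE
  anchorHad <- 0L
  for (ch in chars) {
    if (ch %in% c(" ", "\t")) next
    if (ch == "(") {
      if (side == "target") parseError("'()' anchors are only valid on the source side")
      if (inAnchor || sawAnchor) parseError("only one '()' anchor is allowed")
      inAnchor <- TRUE
      sawAnchor <- TRUE
      anchorHad <- 0L
    } else if (ch == ")") {
      if (!inAnchor) parseError("')' without matching '('")
      inAnchor <- FALSE
      if (anchorHad == 0L) {
        anchorEmpty <- TRUE
        anchorJunction <- length(tok)
      }
    } else if (ch == "_") {
      nDisp <- nDisp + 1L
      tok[[length(tok) + 1L]] <- list(symbol = paste0("_", nDisp),
                                      letter = NA_character_,
                                      inverted = FALSE, dispersion = TRUE,
                                      plus = FALSE, anchor = inAnchor)
      if (inAnchor) anchorHad <- anchorHad + 1L
    } else if (ch == "+") {
      if (side == "source") parseError("'+' is only valid on the target side")
      if (!length(tok)) parseError("'+' must follow a token")
      if (tok[[length(tok)]]$dispersion) parseError("'+' cannot follow a dispersion")
      tok[[length(tok)]]$plus <- TRUE
    } else if (grepl("^[A-Za-z]$", ch)) {
      inv <- ch %in% base::letters
      if (side == "source" && inv)
        parseError(sprintf("lowercase '%s' is not valid on the source side", ch))
      up <- toupper(ch)
      tok[[length(tok) + 1L]] <- list(symbol = up, letter = up,
                                      inverted = inv, dispersion = FALSE,
                                      plus = FALSE, anchor = inAnchor)
      if (inAnchor) anchorHad <- anchorHad + 1L
    } else {
      parseError(sprintf("unexpected character '%s' in rule", ch))
    }
  }
  if (inAnchor) parseError("'(' without matching ')'")
  if (length(tok)) {
    df <- do.call(rbind, lapply(tok, function(t) as.data.frame(t, stringsAsFactors = FALSE)))
    df$seg <- cumsum(c(0L, utils::head(df$dispersion, -1))) + 1L
  } else {
    df <- emptyTokenFrame()
  }
  list(tokens = df, anchorJunction = anchorJunction, anchorEmpty = anchorEmpty)
}

tokenDisplay <- function(tokens) {
  if (!nrow(tokens)) return(character(0))
  out <- ifelse(tokens$dispersion, "_",
                ifelse(tokens$inverted, tolower(tokens$letter), tokens$letter))
  paste0(out, ifelse(tokens$plus, "+", ""))
}

canonicalString <- function(source, target, anchorSymbols, anchorJunction) {
  srcDisp <- tokenDisplay(source)
  if (length(anchorSymbols)) {
    idx <- which(source$anchor)
    srcDisp[min(idx)] <- paste0("(", srcDisp[min(idx)])
    srcDisp[max(idx)] <- paste0(srcDisp[max(idx)], ")")
  } else if (!is.na(anchorJunction)) {
    srcDisp <- append(srcDisp, "()", after = anchorJunction)
  }
  paste0(paste(srcDisp, collapse = ""), "→",
         paste(tokenDisplay(target), collapse = ""))
}

#' Parse a rearrangement expression
#'
#' Accepts both the ASCII \code{"->"} and the Unicode arrow as side
#' separator. See [RearrangementRule-class] for grammar semantics.
#'
#' @param expression a rearrangement string, e.g. \code{"ABC->AC"} (a
#'   deletion of B) or \code{"A_->A_A"} (a dispersed duplication of A).
#' @return a [RearrangementRule-class].
#' @examples
#' parseRule("ABC->AABCC")   # tandem duplication of A and C
#' parseRule("A(B)C->b")     # anchored deletion-flanked inversion
#' @export
parseRule <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || is.na(expression))
    parseError("expression must be a single string")
  norm <- gsub("->", "→", expression, fixed = TRUE)
  nArrow <- lengths(regmatches(norm, gregexpr("→", norm)))
  if (nArrow != 1L)
    parseError(sprintf("rule '%s' must contain exactly one arrow separator", expression))
  pos <- regexpr("→", norm)
  srcText <- substr(norm, 1L, pos - 1L)
  tgtText <- substr(norm, pos + 1L, nchar(norm))
  src <- tokenizeSide(srcText, "source")
  tgt <- tokenizeSide(tgtText, "target")
  s <- src$tokens
  t <- tgt$tokens
  srcLetters <- s$letter[!s$dispersion]
  if (anyDuplicated(srcLetters))
    parseError(sprintf("source letter '%s' repeats",
                       srcLetters[duplicated(srcLetters)][1]))
  if (sum(s$dispersion) != sum(t$dispersion))
    parseError("dispersion ('_') count must match between source and target")
  anchorSymbols <- s$letter[s$anchor & !s$dispersion]
  anchorJunction <- if (src$anchorEmpty) src$anchorJunction else NA_integer_
  rule <- new("RearrangementRule", source = s, target = t,
              canonical = "", anchorSymbols = anchorSymbols,
              anchorJunction = anchorJunction)
  rule@canonical <- canonicalString(s, t, anchorSymbols, anchorJunction)
  validObject(rule)
  rule
}

#' Canonical identifier of a rule
#'
#' A deterministic normalized string usable as a VCF annotation; it
#' round-trips through [parseRule()] and is idempotent.
#'
#' @param rule a [RearrangementRule-class].
#' @return a single string, e.g. \code{"ABC→AC"}.
#' @export
ruleIdentifier <- function(rule) {
  stopifnot(is(rule, "RearrangementRule"))
  rule@canonical
}

# Per-segment longest-common-subsequence match between the segment's source
# letters and its target tokens, preferring earliest target occurrences.
# Returns integer vector: for each source-letter row index (global), the
# matched target row index or NA.
matchInPlace <- function(src, tgt) {
  match <- rep(NA_integer_, nrow(src))
  segs <- unique(src$seg[!src$dispersion])
  for (sg in segs) {
    si <- which(!src$dispersion & src$seg == sg)
    ti <- which(!tgt$dispersion & tgt$seg == sg)
    if (!length(si) || !length(ti)) next
    a <- src$letter[si]
    b <- tgt$letter[ti]
    n <- length(a); m <- length(b)
    L <- matrix(0L, n + 1L, m + 1L)
    for (i in n:1) for (j in m:1) {
      L[i, j] <- if (a[i] == b[j]) L[i + 1L, j + 1L] + 1L
                 else max(L[i + 1L, j], L[i, j + 1L])
    }
    i <- 1L; j <- 1L
    while (i <= n && j <= m) {
      if (a[i] == b[j] && L[i, j] == L[i + 1L, j + 1L] + 1L) {
        match[si[i]] <- ti[j]
        i <- i + 1L; j <- j + 1L
      } else if (L[i + 1L, j] >= L[i, j + 1L]) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  match
}

#' Derive the ordered edit operations a rule implies
#'
#' Classifies every target token and every vanishing source letter into one
#' of the edit kinds: a source letter kept at its original relative position
#' is \code{IDENTITY} (or \code{INVERT_IN_PLACE} when lowercase); extra
#' occurrences adjacent to the in-place one are \code{TANDEM_COPY}, other
#' extra occurrences \code{DISPERSED_COPY}; a letter whose sole occurrence
#' moved is \code{CUT_PASTE}; letters missing from the target are
#' \code{DELETE}; target letters absent from the source are
#' \code{NOVEL_INSERT}. Dispersion tokens are untouched reference and yield
#' \code{IDENTITY}.
#'
#' @param rule a [RearrangementRule-class].
#' @return a data.frame with one row per target token (in target order)
#'   followed by one \code{DELETE} row per vanishing source letter; columns
#'   \code{symbol, kind, targetSlot, inverted, plus}.
#' @examples
#' deriveOperations(parseRule("ABC->ACB"))  # CUT_PASTE of B
#' @export
deriveOperations <- function(rule) {
  stopifnot(is(rule, "RearrangementRule"))
  src <- rule@source
  tgt <- rule@target
  srcLetters <- src$letter[!src$dispersion]
  nT <- nrow(tgt)
  kind <- rep(NA_character_, nT)
  symbol <- tgt$symbol
  inPlaceOf <- matchInPlace(src, tgt)   # index into tgt rows, per src row
  isInPlace <- rep(FALSE, nT)
  isInPlace[stats::na.omit(inPlaceOf)] <- TRUE

  if (nT) {
    for (k in seq_len(nT)) {
      if (tgt$dispersion[k]) { kind[k] <- "IDENTITY"; next }
      L <- tgt$letter[k]
      if (!(L %in% srcLetters)) { kind[k] <- "NOVEL_INSERT"; next }
      if (isInPlace[k]) {
        kind[k] <- if (tgt$inverted[k]) "INVERT_IN_PLACE" else "IDENTITY"
      }
    }
    for (srow in which(!src$dispersion)) {
      L <- src$letter[srow]
      occ <- which(!tgt$dispersion & tgt$letter == L)
      if (!length(occ)) next
      m <- inPlaceOf[srow]
      if (!is.na(m)) {
        # contiguous run of occurrences of L containing the in-place token
        run <- m
        kk <- m - 1L
        while (kk >= 1L && kk %in% occ) { run <- c(kk, run); kk <- kk - 1L }
        kk <- m + 1L
        while (kk <= nT && kk %in% occ) { run <- c(run, kk); kk <- kk + 1L }
        for (k in setdiff(occ, m))
          kind[k] <- if (k %in% run) "TANDEM_COPY" else "DISPERSED_COPY"
      } else {
        kind[occ[1]] <- "CUT_PASTE"
        if (length(occ) > 1) kind[occ[-1]] <- "DISPERSED_COPY"
      }
    }
  }
  ops <- data.frame(symbol = symbol, kind = kind,
                    targetSlot = seq_len(nT), inverted = tgt$inverted,
                    plus = tgt$plus, stringsAsFactors = FALSE)
  gone <- setdiff(srcLetters, tgt$letter[!tgt$dispersion])
  if (length(gone)) {
    ops <- rbind(ops, data.frame(symbol = gone, kind = "DELETE",
                                 targetSlot = NA_integer_, inverted = FALSE,
                                 plus = FALSE, stringsAsFactors = FALSE))
  }
  rownames(ops) <- NULL
  ops
}

# Length-bearing symbols of a rule, in configuration order: source letters
# (source order), dispersions, then novel target letters (target order).
lengthBearingSymbols <- function(rule, interchromosomal = FALSE) {
  src <- rule@source
  tgt <- rule@target
  srcLetters <- src$symbol[!src$dispersion]
  disps <- src$symbol[src$dispersion]
  if (interchromosomal) disps <- character(0)  # inter-chrom gap has no length
  novel <- unique(tgt$letter[!tgt$dispersion & !(tgt$letter %in% src$letter)])
  c(srcLetters, disps, novel)
}
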