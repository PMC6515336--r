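# Structure normalization and admission rules.
#
# Order of operations per structure: clear stereo annotations, split into
# components, drop counterions/solvents keeping the largest organic
# component, then judge the retained parent (element whitelist, true-mixture
# and inorganic rules), neutralize protonation states, and canonicalize with
# Open Babel. The canonical, stereo-free SMILES of the parent doubles as the
# structure key used for deduplication, so salt forms and stereoisomers of
# one parent collapse to a single key.

# conventional organic/QSAR element whitelist ("metal and rare atoms" excluded)
ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

KNOWN_TWO_LETTER <- c(
  "He","Li","Be","Ne","Na","Mg","Al","Si","Cl","Ar","Ca","Sc","Ti","Cr","Mn",
  "Fe","Co","Ni","Cu","Zn","Ga","Ge","As","Se","Br","Kr","Rb","Sr","Zr","Nb",
  "Mo","Tc","Ru","Rh","Pd","Ag","Cd","In","Sn","Sb","Te","Xe","Cs","Ba","La",
  "Ce","Pr","Nd","Pm","Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf",
  "Ta","Re","Os","Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra",
  "Ac","Th","Pa","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr")

# Elements of one SMILES component (hydrogens ignored); returns a character
# vector with one entry per heavy atom. Handles bracket atoms, two-letter
# organic-subset symbols and aromatic lowercase atoms.
smiles_elements <- function(s) {
  out <- character(0)
  chars <- strsplit(s, "")[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", s)
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      el <- bracket_element(content)
      if (!identical(el, "H")) out <- c(out, el)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1L])); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      out <- c(out, ch); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      out <- c(out, toupper(ch)); i <- i + 1L
    } else {
      i <- i + 1L  # bonds, ring closures, branches, digits
    }
  }
  out
}

bracket_element <- function(content) {
  content <- sub("^[0-9]*", "", content)       # isotope
  m <- regmatches(content, regexpr("^([A-Za-z][a-z]?)", content))[1]
  if (is.na(m) || !nzchar(m)) stop("cannot parse bracket atom: [", content, "]")
  if (nchar(m) == 2) {
    cap <- paste0(toupper(substr(m, 1, 1)), substr(m, 2, 2))
    # two-letter symbol only if it names a real element; otherwise the second
    # letter is the hydrogen-count marker or trailing syntax (e.g. [NH3+])
    if (substr(m, 2, 2) == "h" || !(cap %in% c(KNOWN_TWO_LETTER, "Se", "Si")))
      m <- substr(m, 1, 1)
  }
  if (m %in% c("b", "c", "n", "o", "p", "s")) return(toupper(m))
  if (m %in% c("se", "as", "te", "si")) {
    return(paste0(toupper(substr(m, 1, 1)), substr(m, 2, 2)))
  }
  m
}

smiles_carbon_count <- function(s) sum(smiles_elements(s) == "C")

# Neutralize protonation states in bracket atoms: a +n charge with >= n
# explicit hydrogens loses n protons; a -n charge on N/O/S/P gains n.
# No bond edits; quaternary cations and exotic charges are left untouched.
neutralize_smiles <- function(s) {
  pat <- "\\[([0-9]*)([A-Za-z][a-z]?)(H([0-9]*))?(([+-])([0-9]*)|(\\++)|(-+))?(:[0-9]+)?\\]"
  m <- gregexpr(pat, s)
  atoms <- regmatches(s, m)[[1]]
  if (!length(atoms)) return(s)
  fixed <- vapply(atoms, neutralize_bracket_atom, character(1))
  regmatches(s, m)[[1]] <- fixed
  s
}

neutralize_bracket_atom <- function(atom) {
  content <- substr(atom, 2, nchar(atom) - 1)
  iso <- regmatches(content, regexpr("^[0-9]+", content))
  rest <- sub("^[0-9]+", "", content)
  el <- regmatches(rest, regexpr("^[A-Za-z][a-z]?", rest))
  sym <- bracket_element(content)
  if (nchar(el) == 2 && !identical(substr(el, 2, 2), tolower(substr(sym, 2, 2))))
    el <- substr(el, 1, 1)
  # guard: bracket_element() may have decided the trailing letter is H-count
  if (nchar(el) != nchar(sym)) el <- substr(el, 1, nchar(sym))
  rest <- sub(paste0("^", el), "", rest)
  hmatch <- regmatches(rest, regexpr("^H[0-9]*", rest))
  hcount <- 0L
  if (length(hmatch) && nzchar(hmatch)) {
    hcount <- if (nchar(hmatch) == 1) 1L else as.integer(substr(hmatch, 2, nchar(hmatch)))
    rest <- sub("^H[0-9]*", "", rest)
  }
  cmatch <- regmatches(rest, regexpr("^(\\+[0-9]*|-[0-9]*|\\++|-+)", rest))
  charge <- 0L
  if (length(cmatch) && nzchar(cmatch)) {
    sign <- if (substr(cmatch, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cmatch)
    mag <- if (nzchar(digits)) as.integer(digits) else nchar(cmatch)
    charge <- sign * mag
    rest <- sub("^(\\+[0-9]*|-[0-9]*|\\++|-+)", "", rest)
  }
  cls <- rest  # atom-class suffix like :1, kept verbatim
  if (charge > 0L && hcount >= charge) {
    hcount <- hcount - charge; charge <- 0L
  } else if (charge < 0L && sym %in% c("N", "O", "S", "P")) {
    hcount <- hcount - charge; charge <- 0L  # charge negative: adds protons
  }
  hpart <- if (hcount > 0L) paste0("H", if (hcount > 1L) hcount else "") else ""
  cpart <- if (charge == 0L) "" else if (charge > 0L) {
    paste0("+", if (charge > 1L) charge else "")
  } else paste0("-", if (charge < -1L) -charge else "")
  paste0("[", paste0(iso, collapse = ""), el, hpart, cpart, cls, "]")
}

# Open Babel properties of a SMILES vector, one try per molecule so a single
# unparsable structure does not poison the batch. Returns a data.frame with
# NA rows on failure.
mol_props <- function(smiles) {
  cols <- c("cansmi", "cansmiNS", "formula", "MW", "logP", "MR", "TPSA",
            "HBD", "HBA1", "HBA2")
  out <- as.data.frame(matrix(NA, length(smiles), length(cols)),
                       stringsAsFactors = FALSE)
  names(out) <- cols
  for (i in seq_along(smiles)) {
    p <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
      ChemmineR::propOB(sdf)
    }, error = function(e) NULL)
    if (!is.null(p) && nrow(p) == 1) {
      for (cc in cols) out[[cc]][i] <- p[[cc]][1]
    }
  }
  num <- c("MW", "logP", "MR", "TPSA", "HBD", "HBA1", "HBA2")
  for (cc in num) out[[cc]] <- as.numeric(out[[cc]])
  out
}

#' Standardize structures and set canonical keys
#'
#' Applies, per record: stereo clearing; component splitting with
#' counterion/solvent stripping (largest organic component kept); rejection of
#' structures whose parent contains elements outside the organic whitelist
#' (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I), of inorganic parents (no
#' carbon) and of
#' true mixtures (two or more components each with >= 4 carbons);
#' protonation-state neutralization; Open Babel canonicalization (aromaticity
#' re-perceived, output kekulizable). Successful records get `smiles` replaced
#' by the canonical parent SMILES and `canonical_key` set to the stereo-free
#' canonical SMILES. The pass is idempotent.
#'
#' @param records compound record data.frame.
#' @return updated records; rejected rows get status `rejected_structure` and
#'   a reason.
#' @export
standardize_structure <- function(records) {
  records <- validate_records(records)
  for (i in seq_len(nrow(records))) {
    if (records$status[i] != "active") next
    res <- standardize_one(records$smiles[i])
    if (is.null(res$error)) {
      records$smiles[i] <- res$smiles
      records$canonical_key[i] <- res$key
    } else {
      records$status[i] <- "rejected_structure"
      records$reason[i] <- res$error
      records$canonical_key[i] <- NA_character_
    }
  }
  records
}

standardize_one <- function(smiles) {
  s <- gsub("@", "", trimws(smiles))
  s <- gsub("[/\\\\]", "-", s)           # directional bonds -> plain single
  comps <- strsplit(s, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (!length(comps)) return(list(error = "empty structure"))
  info <- lapply(comps, function(cp) {
    el <- tryCatch(smiles_elements(cp), error = function(e) NULL)
    if (is.null(el)) return(NULL)
    list(smiles = cp, elements = el, heavy = length(el), carbons = sum(el == "C"))
  })
  if (any(vapply(info, is.null, logical(1))))
    return(list(error = "unparsable component"))
  carbons <- vapply(info, `[[`, numeric(1), "carbons")
  heavy <- vapply(info, `[[`, numeric(1), "heavy")
  organic <- carbons > 0
  if (!any(organic)) return(list(error = "inorganic (no carbon)"))
  if (sum(carbons >= 4) >= 2)
    return(list(error = "mixture: multiple components with >= 4 carbons"))
  # keep the largest organic component (parent); counterions/solvents dropped
  cand <- which(organic)
  parent <- info[[cand[which.max(heavy[cand])]]]
  bad <- setdiff(unique(parent$elements), ALLOWED_ELEMENTS)
  if (length(bad))
    return(list(error = paste0("metal/rare atom(s): ", paste(bad, collapse = ", "))))
  neutral <- tryCatch(neutralize_smiles(parent$smiles), error = function(e) NULL)
  if (is.null(neutral)) return(list(error = "neutralization failed"))
  p <- mol_props(neutral)
  if (is.na(p$cansmiNS[1])) return(list(error = "sanitization failed"))
  list(smiles = p$cansmiNS[1], key = p$cansmiNS[1])
}

#' Apply the carbon-count and molecular-weight admission filters
#'
#' A standardized record is rejected when its parent has fewer than 4 carbon
#' atoms or an average molecular weight above 900 (standard atomic masses).
#' Both boundaries are strict: exactly 4 carbons and exactly MW 900 pass.
#'
#' @param records compound record data.frame, already standardized.
#' @param min_carbons minimum carbon count retained (default 4).
#' @param max_mw maximum molecular weight retained (default 900).
#' @return updated records with status `rejected_size` where applicable.
#' @export
apply_size_filters <- function(records, min_carbons = 4, max_mw = 900) {
  records <- validate_records(records)
  act <- which(records$status == "active")
  if (!length(act)) return(records)
  if (any(is.na(records$canonical_key[act])))
    stop("records must pass standardize_structure() before size filtering")
  props <- mol_props(records$smiles[act])
  for (k in seq_along(act)) {
    i <- act[k]
    nc <- smiles_carbon_count(records$smiles[i])
    mw <- props$MW[k]
    if (nc < min_carbons) {
      records$status[i] <- "rejected_size"
      records$reason[i] <- sprintf("carbon count %d < %d", nc, min_carbons)
    } else if (!is.na(mw) && mw > max_mw) {
      records$status[i] <- "rejected_size"
      records$reason[i] <- sprintf("MW %.2f > %g", mw, max_mw)
    }
  }
  records
}

#' Full standardization pass with an accounting report
#'
#' @param records compound record data.frame.
#' @param min_carbons,max_mw admission bounds, see [apply_size_filters()].
#' @return list with `records` (updated) and `report`, a
#'   `standardization_report` whose counts are conserved:
#'   `passed + rejections == input_count`.
#' @export
standardize_dataset <- function(records, min_carbons = 4, max_mw = 900) {
  input <- validate_records(records)
  pre_rejected <- sum(input$status != "active")
  out <- standardize_structure(input)
  out <- apply_size_filters(out, min_carbons = min_carbons, max_mw = max_mw)
  new_struct <- sum(out$status == "rejected_structure") - pre_rejected
  metal <- sum(out$status == "rejected_structure" &
                 grepl("^metal/rare", out$reason %||% ""), na.rm = TRUE)
  report <- structure(list(
    input_count = nrow(input),
    pre_rejected = pre_rejected,
    rejected_metal_or_rare = metal,
    rejected_mixture_inorganic = sum(
      out$status == "rejected_structure" &
        grepl("^(mixture|inorganic)", out$reason), na.rm = TRUE),
    rejected_other_structure = new_struct - metal - sum(
      out$status == "rejected_structure" &
        grepl("^(mixture|inorganic)", out$reason), na.rm = TRUE),
    rejected_size = sum(out$status == "rejected_size"),
    passed = sum(out$status == "active")
  ), class = "standardization_report")
  list(records = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.standardization_report <- function(x, ...) {
  cat("Standardization report\n")
  cat("  input:                 ", x$input_count, "\n")
  if (x$pre_rejected) cat("  rejected on input:     ", x$pre_rejected, "\n")
  cat("  metal/rare atoms:      ", x$rejected_metal_or_rare, "\n")
  cat("  mixture/inorganic:     ", x$rejected_mixture_inorganic, "\n")
  cat("  other parse failures:  ", x$rejected_other_structure, "\n")
  cat("  size filter (C<4|MW>900):", x$rejected_size, "\n")
  cat("  passed:                ", x$passed, "\n")
  invisible(x)
}
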