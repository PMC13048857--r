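# Archetype assignment: maps the pattern of non-zero, scorable domain
# scores onto one of 14 mechanistic archetypes.  Single-domain and defined
# multi-domain convergence patterns carry their own reference numbers;
# every other combination is a referral row that resolves to a core
# archetype while documenting the remaining domains as modifiers (domain 4,
# neurochemical) or exposure context (domain 5, xenobiotic/metal).

.ARCHETYPE_LABELS <- c(
  "Isolated CYP impairment (isolated metabolic limitation)",
  "Isolated cytokine elevation (isolated immune activation)",
  "Isolated redox depletion (isolated oxidative/mitochondrial stress)",
  "Isolated neurochemical imbalance (isolated autonomic vulnerability)",
  "Isolated xenobiotic/metal burden (exposure without overload)",
  "CYP + cytokine (immune-mediated phenoconversion)",
  "CYP + redox (metabolic-mitochondrial coupling failure)",
  "Cytokine + redox (inflammatory-oxidative amplification)",
  "Cytokine or redox + neurochemical (autonomic destabilization under systemic stress)",
  "CYP or redox + xenobiotic (exogenous load exceeding reserve)",
  "CYP + cytokine + redox (Core-Multi-Axis Metabolic Collapse)",
  "Cytokine + redox + neurochemical (inflammatory-oxidative autonomic failure)",
  "CYP + redox + neurochemical (neuro-metabolic vulnerability)",
  "CYP + cytokine or redox + xenobiotic/metal (Terminal Multi-Axis Overload)"
)

.MOD_ROLE <- c(`4` = "modifier", `5` = "exposure_context/modifier")

.assignment <- function(ref_no, core, modifiers = integer(),
                        referral_trail = character(),
                        dominance_note = NA_character_) {
  list(ref_no = ref_no, core = core, modifiers = modifiers,
       referral_trail = referral_trail, dominance_note = dominance_note)
}

# Resolve one support subset (sorted domain numbers with score >= 1) given
# the full score vector (needed for dominance comparisons).  Total over all
# 31 non-empty subsets.
.resolve_support <- function(support, scores) {
  key <- paste(support, collapse = "+")
  ref_trail <- function(from, to, doc) {
    sprintf("referral: {%s} -> #%d; %s", from, to, doc)
  }
  switch(
    key,
    "1" = .assignment(1L, 1L),
    "2" = .assignment(2L, 2L),
    "3" = .assignment(3L, 3L),
    "4" = .assignment(4L, 4L),
    "5" = .assignment(5L, 5L),
    "1+2" = .assignment(6L, c(1L, 2L)),
    "1+3" = .assignment(7L, c(1L, 3L)),
    "2+3" = .assignment(8L, c(2L, 3L)),
    "2+4" = .assignment(9L, c(2L, 4L)),
    "3+4" = .assignment(9L, c(3L, 4L)),
    "1+5" = .assignment(10L, c(1L, 5L)),
    "3+5" = .assignment(10L, c(3L, 5L)),
    "1+4" = .assignment(1L, 1L, modifiers = 4L,
      referral_trail = ref_trail("CYP + neurochemical", 1L,
                                 "neurochemical documented as modifier")),
    "2+5" = .assignment(2L, 2L, modifiers = 5L,
      referral_trail = ref_trail("cytokine + xenobiotic/metal", 2L,
                                 "xenobiotic/metal documented as modifier")),
    "4+5" = {
      if (scores[5] > scores[4]) {
        .assignment(5L, 5L, modifiers = 4L,
          referral_trail = ref_trail("neurochemical + xenobiotic", 5L,
                                     "xenobiotic dominant; neurochemical as modifier"))
      } else {
        a <- .assignment(4L, 4L, modifiers = 5L,
          referral_trail = ref_trail("neurochemical + xenobiotic", 4L,
                                     "neurochemical dominant; xenobiotic as modifier"))
        if (scores[4] == scores[5]) {
          a$dominance_note <-
            "Domain 4 = Domain 5: lower-domain-number precedence applied"
        }
        a
      }
    },
    "1+2+3" = .assignment(11L, c(1L, 2L, 3L)),
    "1+2+4" = .assignment(6L, c(1L, 2L), modifiers = 4L,
      referral_trail = ref_trail("CYP + cytokine + neurochemical", 6L,
                                 "neurochemical documented as modifier")),
    "2+3+4" = .assignment(12L, c(2L, 3L, 4L)),
    "2+3+5" = .assignment(8L, c(2L, 3L), modifiers = 5L,
      referral_trail = ref_trail("cytokine + redox + xenobiotic/metal", 8L,
                                 "xenobiotic/metal documented as exposure context")),
    "1+3+4" = .assignment(13L, c(1L, 3L, 4L)),
    "1+4+5" = .assignment(10L, c(1L, 5L), modifiers = 4L,
      referral_trail = ref_trail("CYP + neurochemical + xenobiotic/metal", 10L,
                                 "neurochemical documented as modifier")),
    "3+4+5" = .assignment(10L, c(3L, 5L), modifiers = 4L,
      referral_trail = ref_trail("redox + neurochemical + xenobiotic/metal", 10L,
                                 "neurochemical documented as modifier")),
    "2+4+5" = {
      if (scores[5] > scores[2]) {
        a <- .assignment(5L, 5L, modifiers = c(2L, 4L),
          referral_trail = ref_trail(
            "cytokine + neurochemical + xenobiotic/metal", 5L,
            "Domain 5 score exceeds Domain 2; Domains 2 and 4 as modifiers"))
        a$dominance_note <- "Domain 5 score > Domain 2 score"
        a
      } else {
        .assignment(2L, 2L, modifiers = c(4L, 5L),
          referral_trail = ref_trail(
            "cytokine + neurochemical + xenobiotic/metal", 2L,
            "xenobiotic/metal as exposure context, neurochemical as modifier"))
      }
    },
    "1+2+5" = .assignment(14L, c(1L, 2L, 5L)),
    "1+3+5" = .assignment(14L, c(1L, 3L, 5L)),
    "1+2+3+4" = .assignment(11L, c(1L, 2L, 3L), modifiers = 4L,
      referral_trail = ref_trail("CYP + cytokine + redox + neurochemical",
                                 11L, "neurochemical documented as modifier")),
    "1+2+3+5" = .assignment(11L, c(1L, 2L, 3L), modifiers = 5L,
      referral_trail = ref_trail("CYP + cytokine + redox + xenobiotic", 11L,
        "xenobiotic/metal documented as modifier (possible concurrent overload pressure)")),
    "1+2+4+5" = .assignment(14L, c(1L, 2L, 5L), modifiers = 4L,
      referral_trail = ref_trail(
        "CYP + cytokine + neurochemical + xenobiotic", 14L,
        "via CYP + cytokine + xenobiotic/metal; neurochemical as modifier")),
    "1+3+4+5" = .assignment(14L, c(1L, 3L, 5L), modifiers = 4L,
      referral_trail = ref_trail(
        "CYP + redox + neurochemical + xenobiotic", 14L,
        "via CYP + redox + xenobiotic/metal; neurochemical as modifier")),
    "2+3+4+5" = .assignment(8L, c(2L, 3L), modifiers = c(4L, 5L),
      referral_trail = ref_trail(
        "cytokine + redox + neurochemical + xenobiotic", 8L,
        "neurochemical as modifier, xenobiotic/metal as exposure context")),
    "1+2+3+4+5" = .assignment(11L, c(1L, 2L, 3L), modifiers = c(4L, 5L),
      referral_trail = ref_trail(
        "all five domains", 11L,
        "neurochemical as modifier, xenobiotic/metal as exposure context")),
    stop("internal error: unmapped support subset {", key, "}", call. = FALSE)
  )
}

#' Assign the mechanistic archetype for a domain score pattern
#'
#' The support of a score vector is the set of domains with a scorable,
#' non-zero ordinal. Every one of the 31 non-empty support subsets resolves
#' to exactly one of 14 core archetypes, either directly or through a
#' referral row that documents the remaining domains as modifiers (domain
#' 4) or exposure context (domain 5). Two subsets carry score-dominance
#' conditions: neurochemical + xenobiotic resolves to whichever isolated
#' archetype is dominant (ties to the neurochemical side, noted), and
#' cytokine + neurochemical + xenobiotic resolves to the isolated
#' xenobiotic archetype only when the domain 5 score strictly exceeds
#' domain 2.
#'
#' An NS (not scorable) domain is excluded from the support; when the NS
#' domain is a core domain (1--3) the assignment carries an
#' interpretive-limitation flag. Empty support yields no archetype
#' ("minimal multidomain deviation").
#'
#' @param scores Numeric vector of five domain ordinals (0--3), `NA` for NS,
#'   ordered domain 1 to 5.
#' @return An object of class `mvi_archetype`: `ref_no` (1--14 or `NA`),
#'   `mechanistic_class`, `core_domains`, `modifier_domains` (data frame
#'   with `domain` and `role`), `referral_trail`, `dominance_note`, `flags`.
#' @examples
#' assign_archetype(c(3, 2, 2, 1, 2))$ref_no  # 11
#' assign_archetype(c(2, 0, 0, 0, 0))$ref_no  # 1
#' @export
assign_archetype <- function(scores) {
  if (length(scores) != 5L) {
    stop("input error: scores must have length 5 (domains 1-5)",
         call. = FALSE)
  }
  if (any(!is.na(scores) & !(scores %in% 0:3))) {
    stop("input error: domain scores must be 0-3 or NS", call. = FALSE)
  }
  scores <- as.integer(scores)
  support <- which(!is.na(scores) & scores >= 1L)
  flags <- character()
  ns_core <- intersect(which(is.na(scores)), 1:3)
  if (length(ns_core)) {
    flags <- sprintf(
      "core domain %d not scorable - interpretive limitation", ns_core)
  }
  if (length(support) == 0L) {
    return(structure(
      list(ref_no = NA_integer_,
           mechanistic_class = "minimal multidomain deviation",
           core_domains = integer(),
           modifier_domains = data.frame(domain = integer(),
                                         role = character()),
           referral_trail = character(),
           dominance_note = NA_character_, flags = flags),
      class = "mvi_archetype"
    ))
  }
  a <- .resolve_support(support, scores)
  structure(
    list(ref_no = a$ref_no,
         mechanistic_class = .ARCHETYPE_LABELS[a$ref_no],
         core_domains = a$core,
         modifier_domains = data.frame(
           domain = a$modifiers,
           role = unname(.MOD_ROLE[as.character(a$modifiers)])),
         referral_trail = a$referral_trail,
         dominance_note = a$dominance_note, flags = flags),
    class = "mvi_archetype"
  )
}

#' Enumerate the full archetype lookup map
#'
#' Audits the assignment engine by resolving all 31 non-empty support
#' subsets, including both branches of each score-dominance condition, and
#' tabulating the outcome. Useful for export and for verifying that the map
#' is total, that referrals resolve to core archetypes in at most two hops,
#' and that exactly 14 distinct core archetypes exist.
#'
#' @return A data frame with one row per subset (plus one per conditional
#'   branch): `subset`, `n_domains`, `condition`, `ref_no`,
#'   `mechanistic_class`, `core_domains`, `modifier_domains`, `referral`
#'   (logical), `hops` (0 for direct rows, 1 for referral rows).
#' @examples
#' map <- enumerate_archetype_map()
#' length(unique(map$ref_no))  # 14
#' @export
enumerate_archetype_map <- function() {
  subsets <- unlist(lapply(1:5, function(k) {
    apply(utils::combn(5, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  # representative score vectors; conditional subsets get one per branch
  variants <- function(domains) {
    base <- integer(5)
    base[domains] <- 1L
    key <- paste(domains, collapse = "+")
    if (key == "4+5") {
      v <- list(`D4>D5` = replace(base, 4L, 2L),
                `D5>D4` = replace(base, 5L, 2L),
                `D4=D5` = base)
    } else if (key == "2+4+5") {
      v <- list(`D5>D2` = replace(base, 5L, 2L),
                `D5<=D2` = base)
    } else {
      v <- list(base)
      names(v) <- ""
    }
    v
  }
  rows <- list()
  for (domains in subsets) {
    vs <- variants(domains)
    for (j in seq_along(vs)) {
      cond <- names(vs)[j]
      a <- assign_archetype(vs[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(domains, collapse = "+"),
        n_domains = length(domains),
        condition = cond,
        ref_no = a$ref_no,
        mechanistic_class = a$mechanistic_class,
        core_domains = paste(a$core_domains, collapse = "+"),
        modifier_domains = paste(a$modifier_domains$domain, collapse = "+"),
        referral = length(a$referral_trail) > 0L,
        hops = as.integer(length(a$referral_trail) > 0L),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.mvi_archetype <- function(x, ...) {
  if (is.na(x$ref_no)) {
    cat("Archetype: none (", x$mechanistic_class, ")\n", sep = "")
  } else {
    cat(sprintf("Archetype #%d: %s\n", x$ref_no, x$mechanistic_class))
    cat("  core domains:", paste(x$core_domains, collapse = ", "), "\n")
    if (nrow(x$modifier_domains)) {
      cat("  modifiers:",
          paste(sprintf("D%d (%s)", x$modifier_domains$domain,
                        x$modifier_domains$role), collapse = "; "), "\n")
    }
    for (r in x$referral_trail) cat("  ", r, "\n", sep = "")
    if (!is.na(x$dominance_note)) cat("  note:", x$dominance_note, "\n")
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
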