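# HPbCD topology handling and the ADD hydroxyl parameter patch.
#
# The topology dialect is a strict, documented subset of the common itp
# format: a [ moleculetype ] section (name, variant), an [ atomtypes ]
# section (type, sigma in nm, epsilon in kJ/mol) and an [ atoms ] section
# (nr, name, type, charge in e). Epsilon/sigma are denormalised onto atoms
# after parsing, because the CHARMM36 variant assigns different hydroxyl-O
# epsilons to the glucopyranose and hydroxypropyl moieties. Group tags
# (which atoms are hydroxyl O/H of which moiety) come from an embedded
# [ tags ] section or a YAML tag map; each hydroxyl H is paired with the
# nearest preceding hydroxyl O of the same moiety.
#
# The ADD patch: every hydroxyl H charge goes from its CHARMM36 value
# (0.42 e) to 0.33 e, the per-hydroxyl deficit (+0.09 e) is added to the
# bonded hydroxyl O to preserve neutrality (a user charge map can override
# this redistribution), and the four hydroxyl Lennard-Jones epsilons are set
# to the ADD values. Sigma is never touched.

ADD_HYDROXYL_H_CHARGE <- 0.33
CHARMM36_HYDROXYL_H_CHARGE <- 0.42

HYDROXYL_TAGS <- c("glucopyranose_hydroxyl_O", "glucopyranose_hydroxyl_H",
                   "hydroxypropyl_hydroxyl_O", "hydroxypropyl_hydroxyl_H")

#' Hydroxyl Lennard-Jones epsilon table for a force-field variant
#'
#' @param variant `"original_charmm36"` or `"ADD"`.
#' @return data.frame with columns `moiety`, `element`, `epsilon` (kJ/mol).
#' @export
epsilon_table <- function(variant = c("original_charmm36", "ADD")) {
  variant <- match.arg(variant)
  eps <- if (variant == "original_charmm36") {
    c(gluco_O = 0.804, gluco_H = 0.192, hp_O = 0.636, hp_H = 0.192)
  } else {
    c(gluco_O = 0.450, gluco_H = 0.120, hp_O = 0.450, hp_H = 0.120)
  }
  data.frame(
    moiety = c("glucopyranose", "glucopyranose",
               "hydroxypropyl", "hydroxypropyl"),
    element = c("O", "H", "O", "H"),
    epsilon = unname(eps)
  )
}

tag_to_moiety_element <- function(tag) {
  m <- regmatches(tag, regexec("^(glucopyranose|hydroxypropyl)_hydroxyl_([OH])$",
                               tag))[[1L]]
  if (length(m) != 3L) return(NULL)
  list(moiety = m[2L], element = m[3L])
}

validate_topology <- function(top) {
  atoms <- top$atoms
  total_q <- sum(atoms$charge)
  if (abs(total_q) > 1e-6) {
    stop(sprintf("molecule is not neutral: total charge %.6f e", total_q),
         call. = FALSE)
  }
  h_rows <- which(atoms$group_tag %in%
                    c("glucopyranose_hydroxyl_H", "hydroxypropyl_hydroxyl_H"))
  if (any(is.na(atoms$hydroxyl_o_partner[h_rows]))) {
    stop("every hydroxyl H must be paired with a bonded hydroxyl O",
         call. = FALSE)
  }
  invisible(top)
}

# Pair each hydroxyl H with the nearest preceding hydroxyl O of the same
# moiety (hydroxyl O and H are adjacent in any sane topology).
pair_hydroxyls <- function(atoms) {
  atoms$hydroxyl_o_partner <- NA_integer_
  for (moiety in c("glucopyranose", "hydroxypropyl")) {
    o_tag <- paste0(moiety, "_hydroxyl_O")
    h_tag <- paste0(moiety, "_hydroxyl_H")
    o_rows <- which(atoms$group_tag == o_tag)
    for (h in which(atoms$group_tag == h_tag)) {
      prev_o <- o_rows[o_rows < h]
      if (!length(prev_o)) {
        stop(sprintf("hydroxyl H '%s' (atom %d) has no preceding hydroxyl O to bond to",
                     atoms$name[h], atoms$nr[h]), call. = FALSE)
      }
      atoms$hydroxyl_o_partner[h] <- max(prev_o)
    }
  }
  atoms
}

new_topology <- function(molecule_name, variant, atoms) {
  atoms <- pair_hydroxyls(atoms)
  top <- structure(
    list(molecule_name = molecule_name, variant = variant, atoms = atoms),
    class = "kb_topology"
  )
  validate_topology(top)
}

#' @export
print.kb_topology <- function(x, ...) {
  nh <- sum(x$atoms$group_tag %in%
              c("glucopyranose_hydroxyl_H", "hydroxypropyl_hydroxyl_H"))
  cat(sprintf(
    "kb_topology '%s' (%s): %d atoms, %d hydroxyl groups, total charge %.6f e\n",
    x$molecule_name, x$variant, nrow(x$atoms), nh, sum(x$atoms$charge)))
  invisible(x)
}

#' Load a topology from the documented itp-like dialect
#'
#' Parses the `[ moleculetype ]`, `[ atomtypes ]`, `[ atoms ]` and optional
#' `[ tags ]` sections, denormalises sigma/epsilon onto atoms, assigns group
#' tags (embedded `[ tags ]` section, overridden by `tag_map` when given;
#' untagged atoms are `"other"`), pairs hydroxyl H atoms with their bonded
#' O, and validates neutrality to 1e-6 e.
#'
#' @param path path to the topology file.
#' @param tag_map optional tag map: a named list
#'   `list(<group_tag> = c(atom names...))` or the path of a YAML file with
#'   a top-level `tags:` mapping.
#' @return an object of class `kb_topology`.
#' @export
load_topology <- function(path, tag_map = NULL) {
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  mol <- NULL
  types <- list()
  atoms <- list()
  tags <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("[][ ]", "", ln))
      next
    }
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (is.na(section)) stop("content before any [ section ]", call. = FALSE)
    if (section == "moleculetype") {
      mol <- list(name = toks[1L],
                  variant = if (length(toks) >= 2L) toks[2L]
                            else "original_charmm36")
    } else if (section == "atomtypes") {
      if (length(toks) < 3L) stop("atomtypes line needs: type sigma epsilon",
                                  call. = FALSE)
      types[[toks[1L]]] <- c(sigma = as.numeric(toks[2L]),
                             epsilon = as.numeric(toks[3L]))
    } else if (section == "atoms") {
      if (length(toks) < 4L) {
        stop("atoms line needs: nr name type charge", call. = FALSE)
      }
      atoms[[length(atoms) + 1L]] <-
        data.frame(nr = as.integer(toks[1L]), name = toks[2L],
                   type = toks[3L], charge = as.numeric(toks[4L]))
    } else if (section == "tags") {
      tags[[toks[1L]]] <- toks[2L]
    }
  }
  if (is.null(mol)) stop("missing [ moleculetype ] section", call. = FALSE)
  if (!length(atoms)) stop("missing [ atoms ] section", call. = FALSE)
  atoms <- do.call(rbind, atoms)
  if (any(is.na(atoms$charge))) stop("non-numeric charge column",
                                     call. = FALSE)
  missing_types <- setdiff(unique(atoms$type), names(types))
  if (length(missing_types)) {
    stop(sprintf("atom types without nonbonded parameters: %s",
                 paste(missing_types, collapse = ", ")), call. = FALSE)
  }
  atoms$sigma <- vapply(atoms$type, function(t) types[[t]]["sigma"],
                        numeric(1))
  atoms$epsilon <- vapply(atoms$type, function(t) types[[t]]["epsilon"],
                          numeric(1))
  # group tags: embedded section first, then the user map on top
  name_tags <- unlist(tags)
  if (!is.null(tag_map)) {
    if (is.character(tag_map) && length(tag_map) == 1L) {
      tag_map <- yaml::read_yaml(tag_map)$tags
    }
    for (tg in names(tag_map)) {
      for (nm in tag_map[[tg]]) name_tags[nm] <- tg
    }
  }
  atoms$group_tag <- ifelse(atoms$name %in% names(name_tags),
                            unname(name_tags[atoms$name]), "other")
  bad <- setdiff(unique(atoms$group_tag), c(HYDROXYL_TAGS, "other"))
  if (length(bad)) {
    stop(sprintf("unknown group tags: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  new_topology(mol$name, mol$variant, atoms)
}

#' Apply the ADD hydroxyl parameter patch
#'
#' Sets every hydroxyl H partial charge to 0.33 e, adds each H's charge
#' deficit (its previous charge minus 0.33 e; +0.09 e coming from CHARMM36)
#' to the bonded hydroxyl O so the molecule stays neutral, and replaces the
#' four hydroxyl Lennard-Jones epsilons with the ADD values (0.450 kJ/mol
#' for O, 0.120 kJ/mol for H, both moieties). Sigma and all non-hydroxyl
#' parameters are untouched. Refuses already-patched input.
#'
#' If `charge_map` is supplied (named numeric vector `name -> charge`, or a
#' YAML file with a top-level `charges:` mapping) it overrides the local O
#' redistribution as the authoritative charge set; neutrality and the 0.33 e
#' hydroxyl-H value are then validated rather than constructed.
#'
#' @param top a `kb_topology` with `variant = "original_charmm36"`.
#' @param charge_map optional authoritative per-atom-name charge map.
#' @return the patched `kb_topology` (`variant = "ADD"`).
#' @export
apply_add_patch <- function(top, charge_map = NULL) {
  stopifnot(inherits(top, "kb_topology"))
  if (identical(top$variant, "ADD")) {
    stop("topology already carries the ADD variant; refusing to patch twice",
         call. = FALSE)
  }
  atoms <- top$atoms
  h_tags <- c("glucopyranose_hydroxyl_H", "hydroxypropyl_hydroxyl_H")
  h_rows <- which(atoms$group_tag %in% h_tags)
  if (!length(h_rows)) {
    stop("no tagged hydroxyl hydrogens; check the tag map", call. = FALSE)
  }
  if (!is.null(charge_map)) {
    if (is.character(charge_map) && length(charge_map) == 1L) {
      cm <- yaml::read_yaml(charge_map)$charges
      charge_map <- stats::setNames(as.numeric(unlist(cm)), names(cm))
    }
    hit <- atoms$name %in% names(charge_map)
    atoms$charge[hit] <- unname(charge_map[atoms$name[hit]])
    if (any(abs(atoms$charge[h_rows] - ADD_HYDROXYL_H_CHARGE) > 1e-6)) {
      stop(sprintf("charge map must give every hydroxyl H %.2f e",
                   ADD_HYDROXYL_H_CHARGE), call. = FALSE)
    }
  } else {
    for (h in h_rows) {
      deficit <- atoms$charge[h] - ADD_HYDROXYL_H_CHARGE
      atoms$charge[h] <- ADD_HYDROXYL_H_CHARGE
      o <- atoms$hydroxyl_o_partner[h]
      atoms$charge[o] <- atoms$charge[o] + deficit
    }
  }
  eps <- epsilon_table("ADD")
  for (tg in HYDROXYL_TAGS) {
    me <- tag_to_moiety_element(tg)
    val <- eps$epsilon[eps$moiety == me$moiety & eps$element == me$element]
    atoms$epsilon[atoms$group_tag == tg] <- val
  }
  new_topology(top$molecule_name, "ADD", atoms)
}

#' Field-level difference report between two topologies
#'
#' Requires identical atom lists (nr, name, type); reports every atom whose
#' `charge`, `epsilon` or `sigma` differs. After [apply_add_patch()] the
#' report must touch nothing but hydroxyl O/H charges and hydroxyl epsilons.
#'
#' @param a,b `kb_topology` objects with the same atom list.
#' @param tol numeric comparison tolerance.
#' @return data.frame with columns `nr`, `name`, `group_tag`, `field`,
#'   `old`, `new` (zero rows when identical).
#' @export
diff_topologies <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "kb_topology"), inherits(b, "kb_topology"))
  if (nrow(a$atoms) != nrow(b$atoms) ||
      !identical(a$atoms$name, b$atoms$name) ||
      !identical(a$atoms$type, b$atoms$type)) {
    stop("atom lists differ; topologies are not comparable", call. = FALSE)
  }
  out <- list()
  for (field in c("charge", "epsilon", "sigma")) {
    idx <- which(abs(a$atoms[[field]] - b$atoms[[field]]) > tol)
    if (length(idx)) {
      out[[field]] <- data.frame(
        nr = a$atoms$nr[idx], name = a$atoms$name[idx],
        group_tag = a$atoms$group_tag[idx], field = field,
        old = a$atoms[[field]][idx], new = b$atoms[[field]][idx])
    }
  }
  if (!length(out)) {
    return(data.frame(nr = integer(0), name = character(0),
                      group_tag = character(0), field = character(0),
                      old = numeric(0), new = numeric(0)))
  }
  do.call(rbind, unname(out))
}

#' Write a topology in the documented itp-like dialect
#'
#' Charges are written with 4 decimals, epsilon with 3 and sigma with 4, so
#' repeated writes are byte-identical. Group tags are embedded in a
#' `[ tags ]` section, making the file self-contained for round trips.
#'
#' @param top a `kb_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "kb_topology"))
  atoms <- top$atoms
  # per-type nonbonded table; refuse if the patch made one type ambiguous
  tt <- unique(data.frame(type = atoms$type, sigma = atoms$sigma,
                          epsilon = atoms$epsilon))
  if (anyDuplicated(tt$type)) {
    stop("atoms of one type carry different nonbonded parameters; cannot serialise per type",
         call. = FALSE)
  }
  tagged <- atoms[atoms$group_tag != "other", c("name", "group_tag")]
  tagged <- unique(tagged)
  if (anyDuplicated(tagged$name)) {
    stop("an atom name maps to several group tags; cannot serialise",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("; kbsolv topology dialect (itp subset)",
               "[ moleculetype ]",
               "; name  variant",
               sprintf("%s  %s", top$molecule_name, top$variant),
               "",
               "[ atomtypes ]",
               "; type  sigma_nm  epsilon_kJmol"), con)
  writeLines(sprintf("%-8s %8.4f %8.3f", tt$type, tt$sigma, tt$epsilon), con)
  writeLines(c("", "[ atoms ]", "; nr  name  type  charge_e"), con)
  writeLines(sprintf("%4d  %-6s %-8s %9.4f", atoms$nr, atoms$name,
                     atoms$type, atoms$charge), con)
  if (nrow(tagged)) {
    writeLines(c("", "[ tags ]", "; name  group_tag"), con)
    writeLines(sprintf("%-6s %s", tagged$name, tagged$group_tag), con)
  }
  invisible(path)
}
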