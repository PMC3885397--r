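#' Histological classification of ovary development
#'
#' A deterministic rule engine mapping the histological features of an ovary
#' section to one of eight development classes (C1--C7, with C6 split into
#' C6a/C6b) and a maturity call. Classification uses four features: the most
#' advanced group of oocytes (MAGO), presence of postovulatory follicles
#' (POFs), alpha/beta-stage atresia of yolked oocytes, and maturity markers
#' (gamma/delta atresia "brown bodies" or residual hydrated oocytes).
#'
#' @name histology
NULL

MAGO_LEVELS <- c("unyolked", "early_yolked", "advanced_yolked",
                 "migratory_nucleus", "hydrated")
ALPHA_LEVELS <- c("none", "lt50", "ge50", "full")
DEV_CLASSES <- c("C1", "C2", "C3", "C4", "C5", "C6a", "C6b", "C7")

#' Construct an ovary snapshot
#'
#' @param mago Most advanced group of oocytes: one of `"unyolked"`,
#'   `"early_yolked"`, `"advanced_yolked"`, `"migratory_nucleus"`,
#'   `"hydrated"`.
#' @param pofs_present Logical; postovulatory follicles present.
#' @param alpha_atresia Alpha-stage atresia of yolked oocytes, as an ordinal:
#'   `"none"`, `"lt50"` (<50\% of yolked oocytes), `"ge50"`, or `"full"`
#'   (100\%: no intact advanced oocytes remain, so `mago` must be unyolked or
#'   early yolked).
#' @param beta_atresia_present Logical; beta-stage atresia present.
#' @param maturity_markers_present Logical; gamma/delta atresia (brown bodies)
#'   or residual hydrated oocytes present.
#' @return An object of class `ovary_snapshot`.
#' @export
#' @examples
#' ovary_snapshot("advanced_yolked", FALSE, "none", FALSE, FALSE)
ovary_snapshot <- function(mago, pofs_present, alpha_atresia = "none",
                           beta_atresia_present = FALSE,
                           maturity_markers_present = FALSE) {
  mago <- match.arg(mago, MAGO_LEVELS)
  alpha_atresia <- match.arg(alpha_atresia, ALPHA_LEVELS)
  stopifnot(is.logical(pofs_present), length(pofs_present) == 1L,
            is.logical(beta_atresia_present),
            is.logical(maturity_markers_present))
  if (alpha_atresia == "full" &&
      !mago %in% c("unyolked", "early_yolked")) {
    stop("invalid ovary snapshot: alpha_atresia = \"full\" implies no intact ",
         "advanced oocytes remain, so mago must be \"unyolked\" or ",
         "\"early_yolked\" (got \"", mago, "\")", call. = FALSE)
  }
  structure(list(mago = mago,
                 pofs_present = pofs_present,
                 alpha_atresia = alpha_atresia,
                 beta_atresia_present = beta_atresia_present,
                 maturity_markers_present = maturity_markers_present),
            class = "ovary_snapshot")
}

#' Classify an ovary into a development class
#'
#' Implements the standard histological staging for a batch-spawning tuna
#' ovary. Rows are evaluated most-advanced-evidence first (C4, C3, C5, C6a,
#' C6b, C7, C2, C1), so an ovary showing both spawning evidence and atresia is
#' scored by its most advanced feature:
#' \describe{
#'   \item{C4 (spawning)}{MAGO migratory nucleus or hydrated, and/or POFs;
#'     <50\% alpha atresia.}
#'   \item{C3 (spawning capable)}{MAGO advanced yolked, no POFs; <50\% alpha
#'     atresia.}
#'   \item{C5 (regressing)}{MAGO advanced yolked, no POFs; >=50\% alpha
#'     atresia.}
#'   \item{C6a (regressed 1)}{MAGO unyolked/early yolked, no POFs; 100\% alpha
#'     atresia.}
#'   \item{C6b (regressed 2)}{MAGO unyolked/early yolked, no POFs; no alpha
#'     but beta atresia present.}
#'   \item{C7 (regenerating)}{MAGO unyolked/early yolked, no POFs, no
#'     alpha/beta atresia; maturity markers present.}
#'   \item{C2 (developing)}{MAGO early yolked, nothing else.}
#'   \item{C1 (immature)}{MAGO unyolked, nothing else.}
#' }
#'
#' @param snapshot An [ovary_snapshot()].
#' @return A single character development class, one of
#'   `c("C1","C2","C3","C4","C5","C6a","C6b","C7")`.
#' @export
classify_ovary <- function(snapshot) {
  if (!inherits(snapshot, "ovary_snapshot")) {
    snapshot <- do.call(ovary_snapshot, as.list(snapshot))
  }
  s <- snapshot
  spawning_evidence <- s$mago %in% c("migratory_nucleus", "hydrated") ||
    s$pofs_present
  active_clutch <- s$mago %in% c("advanced_yolked", "migratory_nucleus",
                                 "hydrated") || s$pofs_present
  inactive_mago <- s$mago %in% c("unyolked", "early_yolked")
  alpha_lt50 <- s$alpha_atresia %in% c("none", "lt50")

  # active classes: "<50% alpha atresia" includes none; C4's "and/or POF's"
  if (spawning_evidence && alpha_lt50) return("C4")
  if (s$mago == "advanced_yolked" && !s$pofs_present && alpha_lt50) {
    return("C3")
  }
  # regressing: an advanced clutch (or POFs) overtaken by heavy atresia
  if (active_clutch && !alpha_lt50) return("C5")
  if (inactive_mago && !s$pofs_present && s$alpha_atresia == "full") {
    return("C6a")
  }
  # regressed 2: residual alpha or beta atresia without an advanced clutch
  if (inactive_mago && !s$pofs_present &&
      (s$alpha_atresia %in% c("lt50", "ge50") || s$beta_atresia_present)) {
    return("C6b")
  }
  if (inactive_mago && !s$pofs_present && s$alpha_atresia == "none" &&
      !s$beta_atresia_present && s$maturity_markers_present) {
    return("C7")
  }
  if (s$mago == "early_yolked") {
    return("C2")
  }
  if (s$mago == "unyolked") {
    return("C1")
  }
  stop("unclassifiable ovary snapshot", call. = FALSE) # nocov
}

#' Maturity status and activity implied by a development class
#'
#' Classes C1--C2 are immature; C3--C4 are mature and reproductively active
#' (spawning capable or spawning); C5, C6a, C6b and C7 are mature but inactive
#' (regressing, regressed or regenerating).
#'
#' @param dev_class Development class (`"C1"`..`"C7"`), or `NA` for a fish not
#'   examined histologically.
#' @param fork_length_cm Fork length in cm. Fish under 70 cm may be classed
#'   immature on macroscopic examination alone (class absent); histology is
#'   required at or above 70 cm.
#' @param macro_threshold_cm Macroscopic-immature length threshold (cm).
#' @return A list with `status` (`"mature"`/`"immature"`) and `activity`
#'   (`"active"`/`"inactive"`/`"not_applicable"`).
#' @export
#' @examples
#' assign_maturity("C7", 88)    # mature, inactive (regenerating)
#' assign_maturity(NA, 55)      # immature on macroscopic examination
assign_maturity <- function(dev_class, fork_length_cm,
                            macro_threshold_cm = 70) {
  stopifnot(is.numeric(fork_length_cm), length(fork_length_cm) == 1L,
            fork_length_cm > 0)
  if (length(dev_class) != 1L) stop("dev_class must be a single value")
  if (is.na(dev_class)) {
    if (fork_length_cm >= macro_threshold_cm) {
      stop("histology required: fish of ", fork_length_cm, " cm is at or ",
           "above the ", macro_threshold_cm,
           " cm macroscopic-immature threshold but has no development class",
           call. = FALSE)
    }
    return(list(status = "immature", activity = "not_applicable"))
  }
  dev_class <- match.arg(dev_class, DEV_CLASSES)
  if (dev_class %in% c("C1", "C2")) {
    list(status = "immature", activity = "not_applicable")
  } else if (dev_class %in% c("C3", "C4")) {
    list(status = "mature", activity = "active")
  } else {
    list(status = "mature", activity = "inactive")
  }
}

#' Tabulate development classes and maturity status
#'
#' Counts fish by development class, attaching maturity status and activity,
#' and totals by status. Fish classed immature macroscopically (no development
#' class) are counted under `"macro_immature"`.
#'
#' @param dev_classes Character vector of development classes, `NA` for
#'   macroscopically classed fish.
#' @return A list with `by_class` (data.frame: class, status, activity, n) and
#'   `totals` (named vector with `mature` and `immature`).
#' @export
tabulate_classes <- function(dev_classes) {
  lv <- c(DEV_CLASSES, "macro_immature")
  dc <- ifelse(is.na(dev_classes), "macro_immature", as.character(dev_classes))
  bad <- setdiff(unique(dc), lv)
  if (length(bad)) stop("unknown development class: ", paste(bad, collapse = ", "))
  n <- as.vector(table(factor(dc, levels = lv)))
  status <- c(rep("immature", 2), rep("mature", 6), "immature")
  activity <- c("not_applicable", "not_applicable", "active", "active",
                rep("inactive", 4), "not_applicable")
  by_class <- data.frame(class = lv, status = status, activity = activity,
                         n = n, stringsAsFactors = FALSE)
  totals <- c(mature = sum(n[status == "mature"]),
              immature = sum(n[status == "immature"]))
  list(by_class = by_class, totals = totals)
}

#' Enumerate every valid ovary snapshot
#'
#' Expands the full finite feature grid and drops combinations violating the
#' snapshot invariants. Used to verify that the classification rules are
#' exhaustive and mutually exclusive.
#'
#' @return A data.frame with one row per valid snapshot.
#' @export
enumerate_snapshots <- function() {
  g <- expand.grid(mago = MAGO_LEVELS,
                   pofs_present = c(FALSE, TRUE),
                   alpha_atresia = ALPHA_LEVELS,
                   beta_atresia_present = c(FALSE, TRUE),
                   maturity_markers_present = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  ok <- !(g$alpha_atresia == "full" &
            !g$mago %in% c("unyolked", "early_yolked"))
  g[ok, , drop = FALSE]
}

#' Read an ovary feature table and classify it
#'
#' Reads a delimited text file with one row per ovary and columns named after
#' the snapshot fields (`mago`, `pofs_present`, `alpha_atresia`,
#' `beta_atresia_present`, `maturity_markers_present`; booleans coded 0/1,
#' enums as lower-case tokens), classifies each row, and returns the table
#' with `dev_class` appended.
#'
#' @param path Path to a delimited file (tab or comma; sniffed from header).
#' @return The input data.frame with a `dev_class` column.
#' @export
classify_ovary_table <- function(path) {
  d <- read_delim_sniff(path)
  need <- c("mago", "pofs_present", "alpha_atresia", "beta_atresia_present",
            "maturity_markers_present")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("ovary table is missing column(s): ",
                         paste(miss, collapse = ", "))
  d$dev_class <- vapply(seq_len(nrow(d)), function(i) {
    classify_ovary(ovary_snapshot(
      mago = d$mago[i],
      pofs_present = as.logical(as.integer(d$pofs_present[i])),
      alpha_atresia = d$alpha_atresia[i],
      beta_atresia_present = as.logical(as.integer(d$beta_atresia_present[i])),
      maturity_markers_present =
        as.logical(as.integer(d$maturity_markers_present[i]))))
  }, character(1))
  d
}
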