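## Region ordering used throughout: SM1 = 1, PMd = 2, SMA = 3.
REGIONS <- c("SM1", "PMd", "SMA")

## All connections whose modulation can be switched on in a model.
MODULATED_CONNECTIONS <- c("SMA->SM1", "SM1->SMA", "PMd->SM1", "SM1->PMd",
                           "SMA->PMd", "PMd->SMA",
                           "self-SM1", "self-SMA", "self-PMd")

#' Construct and validate a model specification
#'
#' A model is defined by which connections are modulated by the slowing
#' input (`b_mask`) and which premotor areas receive the driving input
#' (`c_mask`); the endogenous A-matrix is fixed and fully bidirectional in
#' every model.  Validation enforces the design rules: driving input goes
#' to PMd, SMA or both (never SM1); the premotor interaction SMA<->PMd is
#' modulated jointly or not at all; a premotor self-modulation requires a
#' modulated connection between that premotor area and SM1.
#'
#' @param b_mask character vector of modulated connections, a subset of
#'   `"SMA->SM1" "SM1->SMA" "PMd->SM1" "SM1->PMd" "SMA->PMd" "PMd->SMA"
#'   "self-SM1" "self-SMA" "self-PMd"`.
#' @param c_mask driving-input targets, a non-empty subset of
#'   `c("PMd", "SMA")`.
#' @return object of class `model_spec` with fields `id`, `b_mask`,
#'   `c_mask`, `family`, `self_sm1`, `family_label`.
#' @export
model_spec <- function(b_mask, c_mask) {
  b_mask <- sort(unique(as.character(b_mask)))
  c_mask <- sort(unique(as.character(c_mask)))
  bad <- setdiff(b_mask, MODULATED_CONNECTIONS)
  if (length(bad)) stop("unknown connections: ", paste(bad, collapse = ", "))
  if (length(c_mask) == 0 || !all(c_mask %in% c("PMd", "SMA")))
    stop("driving input must target PMd, SMA or both (never SM1)")
  fam <- family_of_masks(b_mask, c_mask)
  id <- sprintf("%s|B=%s|C=%s", fam$label,
                if (length(b_mask)) paste(b_mask, collapse = ",") else "-",
                paste(c_mask, collapse = ","))
  structure(list(id = id, b_mask = b_mask, c_mask = c_mask,
                 family = fam$family, self_sm1 = fam$self_sm1,
                 family_label = fam$label),
            class = "model_spec")
}

family_of_masks <- function(b_mask, c_mask) {
  has <- function(x) x %in% b_mask
  if (has("SMA->PMd") != has("PMd->SMA"))
    stop("SMA->PMd and PMd->SMA must be modulated jointly")
  down <- intersect(c("SMA->SM1", "PMd->SM1"), b_mask)
  up <- intersect(c("SM1->SMA", "SM1->PMd"), b_mask)
  sma_linked <- any(c("SMA->SM1", "SM1->SMA") %in% b_mask)
  pmd_linked <- any(c("PMd->SM1", "SM1->PMd") %in% b_mask)
  if (has("self-SMA") && !sma_linked)
    stop("self-SMA modulation requires a modulated SMA-SM1 connection")
  if (has("self-PMd") && !pmd_linked)
    stop("self-PMd modulation requires a modulated PMd-SM1 connection")
  family <-
    if (length(down) == 0 && length(up) == 0) "null"
    else if (length(up) == 0) "top_down"
    else if (length(down) == 0) "bottom_up"
    else {
      both_sma <- setequal(c(down, up), c("SMA->SM1", "SM1->SMA"))
      both_pmd <- setequal(c(down, up), c("PMd->SM1", "SM1->PMd"))
      if (!(both_sma || both_pmd))
        stop("mixed up/down modulation must be a single bidirectional SM1<->premotor pair")
      "selective"
    }
  if (family == "selective") {
    need <- if (sma_linked) "self-SMA" else "self-PMd"
    if (!has(need))
      stop("selective premotor models include the involved premotor self-modulation")
  }
  self_sm1 <- has("self-SM1")
  list(family = family, self_sm1 = self_sm1,
       label = paste0(family, if (self_sm1) "+selfSM1" else "-selfSM1"))
}

#' Family label of a model
#'
#' Deterministic function of the modulation masks; one of the 8 labels
#' `{top_down, bottom_up, selective, null} x {+selfSM1, -selfSM1}`.
#'
#' @param spec a `model_spec`.
#' @return character family label.
#' @export
family_of <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  family_of_masks(spec$b_mask, spec$c_mask)$label
}

#' Enumerate the full 180-model space
#'
#' Crosses the family cores with the shared factors.  Cores: top-down
#' (modulation of SMA->SM1, PMd->SM1 or both, each with or without the
#' involved premotor self-modulation: 6), bottom-up (mirrored: 6),
#' selective premotor (bidirectional SM1<->SMA or SM1<->PMd, always with
#' the involved premotor self-modulation: 2), null (no SM1-coupled
#' modulation: 1).  Shared factors: premotor interaction SMA<->PMd
#' modulated or not (x2), driving input to PMd, SMA or both (x3), and SM1
#' self-modulation present or absent (x2).  This yields family sizes
#' 36/36/12/6 per SM1-self level, 180 models in 8 families.
#'
#' @return list of `model_spec`, in deterministic order.
#' @export
enumerate_model_space <- function() {
  prem_self <- function(conns) {
    out <- character(0)
    if (any(c("SMA->SM1", "SM1->SMA") %in% conns)) out <- c(out, "self-SMA")
    if (any(c("PMd->SM1", "SM1->PMd") %in% conns)) out <- c(out, "self-PMd")
    out
  }
  cores <- list()
  for (conns in list("SMA->SM1", "PMd->SM1", c("SMA->SM1", "PMd->SM1")))
    for (with_self in c(FALSE, TRUE))
      cores[[length(cores) + 1L]] <-
        c(conns, if (with_self) prem_self(conns))
  for (conns in list("SM1->SMA", "SM1->PMd", c("SM1->SMA", "SM1->PMd")))
    for (with_self in c(FALSE, TRUE))
      cores[[length(cores) + 1L]] <-
        c(conns, if (with_self) prem_self(conns))
  for (conns in list(c("SMA->SM1", "SM1->SMA"), c("PMd->SM1", "SM1->PMd")))
    cores[[length(cores) + 1L]] <- c(conns, prem_self(conns))
  cores[[length(cores) + 1L]] <- character(0)

  space <- list()
  for (core in cores)
    for (pm_interaction in c(FALSE, TRUE))
      for (drive in list("PMd", "SMA", c("PMd", "SMA")))
        for (sm1_self in c(FALSE, TRUE)) {
          b <- core
          if (pm_interaction) b <- c(b, "SMA->PMd", "PMd->SMA")
          if (sm1_self) b <- c(b, "self-SM1")
          space[[length(space) + 1L]] <- model_spec(b, drive)
        }
  ids <- vapply(space, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("internal error: duplicate model specs")
  space
}

#' Tabulate family sizes of a model space
#'
#' @param space list of `model_spec` (default: the full space).
#' @return named integer vector of counts per family label.
#' @export
family_sizes <- function(space = enumerate_model_space()) {
  labs <- vapply(space, `[[`, character(1), "family_label")
  table(factor(labs, levels = sort(unique(labs))))
}

#' Model space as a flat table
#'
#' One row per model: id, family, SM1-self flag, and one 0/1 column per
#' switchable connection plus the driving targets.  Suitable for export as
#' TSV mirroring a supplementary model list.
#'
#' @param space list of `model_spec`.
#' @return data frame.
#' @export
model_space_table <- function(space = enumerate_model_space()) {
  rows <- lapply(space, function(m) {
    on <- as.integer(MODULATED_CONNECTIONS %in% m$b_mask)
    names(on) <- gsub("[->]+", "_", MODULATED_CONNECTIONS)
    cbind(data.frame(id = m$id, family = m$family, self_sm1 = m$self_sm1,
                     drive = paste(m$c_mask, collapse = "+"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(on)))
  })
  do.call(rbind, rows)
}

## Map connection names to matrix positions (row = target, col = source).
.connection_index <- function(name) {
  if (startsWith(name, "self-")) {
    r <- match(sub("self-", "", name), REGIONS)
    return(c(r, r))
  }
  parts <- strsplit(name, "->", fixed = TRUE)[[1]]
  c(match(parts[2], REGIONS), match(parts[1], REGIONS))
}

#' Binary B/C masks as matrices
#'
#' Expands a `model_spec` into a 3x3 0/1 matrix over connections (rows =
#' targets, columns = sources; diagonal = self-modulations) and a length-3
#' 0/1 driving vector over regions.
#'
#' @param spec a `model_spec`.
#' @return list with `B` (3x3) and `C` (length 3, named by region).
#' @export
spec_masks <- function(spec) {
  B <- matrix(0, 3, 3, dimnames = list(REGIONS, REGIONS))
  for (nm in spec$b_mask) {
    ij <- .connection_index(nm)
    B[ij[1], ij[2]] <- 1
  }
  C <- stats::setNames(as.numeric(REGIONS %in% spec$c_mask), REGIONS)
  list(B = B, C = C)
}
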