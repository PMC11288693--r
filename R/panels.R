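#' Panel definitions
#'
#' A panel bundles the channel layout (13 channels: three scatter, time,
#' viability, bead, plus surface markers), the per-population event-level
#' intensity templates used by the synthetic cohort generator, the default
#' gating tree, and the panel's low-abundance phenotype minimum (20 cells/ul
#' for the innate panel, 10 for the adaptive panel).
#'
#' Templates are parameterized on the analysis (asinh) scale so that density
#' gating after transformation sees well-separated Gaussian mixtures;
#' positive and negative marker locations are at least three combined
#' standard deviations apart.
#'
#' @param name `"innate"` or `"adaptive"`.
#' @return A list with `name`, `channels`, `roles`, `transform_cofactor`,
#'   `templates`, `tree`, `min_cells_per_ul`, and `phenotype_markers`.
#' @export
panel_config <- function(name = c("innate", "adaptive")) {
  name <- match.arg(name)
  base_channels <- c("FSC-A", "FSC-H", "SSC-A", "Time", "Viability", "Beads")
  base_roles <- c("scatter", "scatter", "scatter", "time", "viability", "bead")
  markers <- if (name == "innate") {
    c("CD45", "CD66", "CD11b", "CD16", "HLADR", "CD14", "CD56")
  } else {
    c("CD45", "CD66", "CD3", "gd", "CD19", "CD10")
  }
  channels <- c(base_channels, markers)
  roles <- stats::setNames(c(base_roles, rep("marker", length(markers))), channels)
  tpl <- if (name == "innate") innate_templates() else adaptive_templates()
  tree <- if (name == "innate") innate_tree() else adaptive_tree()
  list(name = name, channels = channels, roles = roles,
       transform_cofactor = 150,
       templates = tpl, tree = tree,
       min_cells_per_ul = if (name == "innate") 20 else 10,
       phenotype_markers = markers[-1])   # CD45 is the parent-selection marker
}

# template helper: per-channel (loc, sd) on the analysis scale for markers /
# viability / bead, on the linear scale for scatter.  POS/NEG are asinh-scale
# locations of stained-positive and unstained populations.
POS <- 5.0; NEG <- 0.35; MSD <- 0.35

pop_template <- function(fsc, ssc, markers, viability = 0.3, bead = 0.2,
                         msd = MSD) {
  list(fsc = fsc, ssc = ssc, markers = markers, viability = viability,
       bead = bead, msd = msd)
}

innate_templates <- function() {
  m <- function(...) c(...)
  list(
    MatureNeutrophils = pop_template(90000, 70000,
      m(CD45 = 4.5, CD66 = POS, CD11b = POS, CD16 = POS,
        HLADR = 0.4, CD14 = 0.4, CD56 = 0.3)),
    ImmatureNeutrophils1 = pop_template(85000, 65000,
      m(CD45 = 4.5, CD66 = POS, CD11b = 0.5, CD16 = 0.5,
        HLADR = 0.4, CD14 = 0.4, CD56 = 0.3)),
    ImmatureNeutrophils2 = pop_template(85000, 65000,
      m(CD45 = 4.5, CD66 = POS, CD11b = 0.5, CD16 = 4.8,
        HLADR = 0.4, CD14 = 0.4, CD56 = 0.3)),
    CD11bposCD16negGranulocytes = pop_template(85000, 65000,
      m(CD45 = 4.5, CD66 = POS, CD11b = 4.8, CD16 = 0.5,
        HLADR = 0.4, CD14 = 0.4, CD56 = 0.3)),
    Monocytes = pop_template(82000, 30000,
      m(CD45 = 4.8, CD66 = 0.4, CD11b = 4.0, CD16 = 0.4,
        HLADR = 4.5, CD14 = 4.8, CD56 = 0.3)),
    HLADRposCD14neg = pop_template(80000, 20000,
      m(CD45 = 4.8, CD66 = 0.4, CD11b = 2.0, CD16 = 0.5,
        HLADR = 4.3, CD14 = 0.4, CD56 = 0.3)),
    NKcells = pop_template(78000, 15000,
      m(CD45 = 4.8, CD66 = 0.4, CD11b = 0.5, CD16 = 4.3,
        HLADR = 0.4, CD14 = 0.3, CD56 = 4.3)),
    Lymphocytes = pop_template(78000, 12000,
      m(CD45 = POS, CD66 = 0.3, CD11b = 0.4, CD16 = 0.4,
        HLADR = 0.4, CD14 = 0.3, CD56 = 0.3))
  )
}

adaptive_templates <- function() {
  m <- function(...) c(...)
  list(
    Granulocytes = pop_template(88000, 68000,
      m(CD45 = 4.5, CD66 = POS, CD3 = 0.4, gd = 0.3, CD19 = 0.3, CD10 = 4.2)),
    gdTcells = pop_template(78000, 12000,
      m(CD45 = POS, CD66 = 0.3, CD3 = 4.6, gd = 4.4, CD19 = 0.3, CD10 = 0.3)),
    gdNegTcells = pop_template(78000, 12000,
      m(CD45 = POS, CD66 = 0.3, CD3 = 4.6, gd = 0.4, CD19 = 0.3, CD10 = 0.3)),
    Bcells = pop_template(78000, 12000,
      m(CD45 = POS, CD66 = 0.3, CD3 = 0.4, gd = 0.3, CD19 = 4.4, CD10 = 2.0)),
    OtherLymphocytes = pop_template(78000, 13000,
      m(CD45 = POS, CD66 = 0.3, CD3 = 0.4, gd = 0.3, CD19 = 0.4, CD10 = 0.4))
  )
}

# special (non-gated) event classes shared by both panels
special_templates <- function(markers) {
  list(
    Debris = pop_template(12000, 8000,
      stats::setNames(rep(0.4, length(markers)), markers),
      viability = 0.6, msd = 0.6),
    Dead = pop_template(70000, 30000,
      stats::setNames(rep(2.0, length(markers)), markers),
      viability = 4.5, msd = 1.0),
    Doublets = pop_template(170000, 75000,
      stats::setNames(rep(2.5, length(markers)), markers),
      msd = 1.2),
    Beads = pop_template(40000, 40000,
      stats::setNames(rep(3.0, length(markers)), markers),
      viability = 2.0, bead = 6.5, msd = 0.3)
  )
}

# singlet gate: a band around FSC-H ~ 0.5 FSC-A; doublets fall below it
singlet_polygon <- function() {
  rbind(c(0, -3000), c(262144, 0.32 * 262144),
        c(262144, 0.75 * 262144), c(0, 3000))
}

innate_tree <- function() {
  gating_tree(list(
    Cells = list(parent = "All",
      gate = gate_spec("threshold1d", "Beads", side = "below", threshold = 4)),
    Size = list(parent = "Cells",
      gate = gate_spec("threshold1d", "FSC-A", side = "above",
                       fallback_percentile = 0.05)),
    Singlets = list(parent = "Size",
      gate = gate_spec("polygon", c("FSC-A", "FSC-H"),
                       vertices = singlet_polygon())),
    Live = list(parent = "Singlets",
      gate = gate_spec("threshold1d", "Viability", side = "below",
                       fallback_percentile = 0.995, min_peak_frac = 0.01)),
    Leukocytes = list(parent = "Live",
      gate = gate_spec("threshold1d", "CD45", side = "above",
                       threshold = 2)),
    Granulocytes = list(parent = "Leukocytes",
      gate = gate_spec("threshold1d", "CD66", side = "above")),
    NonGranulocytes = list(parent = "Leukocytes",
      gate = gate_spec("threshold1d", "CD66", side = "below")),
    MatureNeutrophils = list(parent = "Granulocytes",
      gate = gate_spec("rect2d", c("CD11b", "CD16"), side = c("above", "above"))),
    ImmatureNeutrophils1 = list(parent = "Granulocytes",
      gate = gate_spec("rect2d", c("CD11b", "CD16"), side = c("below", "below"))),
    ImmatureNeutrophils2 = list(parent = "Granulocytes",
      gate = gate_spec("rect2d", c("CD11b", "CD16"), side = c("below", "above"))),
    CD11bposCD16negGranulocytes = list(parent = "Granulocytes",
      gate = gate_spec("rect2d", c("CD11b", "CD16"), side = c("above", "below"))),
    Monocytes = list(parent = "NonGranulocytes",
      gate = gate_spec("rect2d", c("HLADR", "CD14"), side = c("above", "above"))),
    HLADRposCD14neg = list(parent = "NonGranulocytes",
      gate = gate_spec("rect2d", c("HLADR", "CD14"), side = c("above", "below"))),
    HLADRnegCD14neg = list(parent = "NonGranulocytes",
      gate = gate_spec("rect2d", c("HLADR", "CD14"), side = c("below", "below"))),
    NKcells = list(parent = "HLADRnegCD14neg",
      gate = gate_spec("rect2d", c("CD56", "CD16"), side = c("above", "above"))),
    Lymphocytes = list(parent = "HLADRnegCD14neg",
      gate = gate_spec("rect2d", c("CD56", "CD16"), side = c("below", "below")))
  ))
}

adaptive_tree <- function() {
  gating_tree(list(
    Cells = list(parent = "All",
      gate = gate_spec("threshold1d", "Beads", side = "below", threshold = 4)),
    Size = list(parent = "Cells",
      gate = gate_spec("threshold1d", "FSC-A", side = "above",
                       fallback_percentile = 0.05)),
    Singlets = list(parent = "Size",
      gate = gate_spec("polygon", c("FSC-A", "FSC-H"),
                       vertices = singlet_polygon())),
    Live = list(parent = "Singlets",
      gate = gate_spec("threshold1d", "Viability", side = "below",
                       fallback_percentile = 0.995, min_peak_frac = 0.01)),
    Leukocytes = list(parent = "Live",
      gate = gate_spec("threshold1d", "CD45", side = "above",
                       threshold = 2)),
    Granulocytes = list(parent = "Leukocytes",
      gate = gate_spec("threshold1d", "CD66", side = "above")),
    NonGranulocytes = list(parent = "Leukocytes",
      gate = gate_spec("threshold1d", "CD66", side = "below")),
    Tcells = list(parent = "NonGranulocytes",
      gate = gate_spec("threshold1d", "CD3", side = "above")),
    NonTcells = list(parent = "NonGranulocytes",
      gate = gate_spec("threshold1d", "CD3", side = "below")),
    gdTcells = list(parent = "Tcells",
      gate = gate_spec("threshold1d", "gd", side = "above")),
    gdNegTcells = list(parent = "Tcells",
      gate = gate_spec("threshold1d", "gd", side = "below")),
    Bcells = list(parent = "NonTcells",
      gate = gate_spec("threshold1d", "CD19", side = "above")),
    OtherLymphocytes = list(parent = "NonTcells",
      gate = gate_spec("threshold1d", "CD19", side = "below"))
  ))
}

#' Default gating tree for a panel
#' @param panel `"innate"` or `"adaptive"`.
#' @return A [gating_tree()].
#' @export
default_gating_tree <- function(panel = "innate") panel_config(panel)$tree
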