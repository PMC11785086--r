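#' Metabolite panel registry
#'
#' A metabolite panel is the ordered name registry shared by the cohort
#' generator, the probit transformer and every downstream score. Each entry
#' carries a `certified` flag marking membership in the clinically certified
#' subset (27 of the 168 absolute NMR measures in the default panel).
#'
#' @param names character vector of unique metabolite identifiers.
#' @param certified logical vector, same length as `names`.
#' @return A `metabolite_panel`: a data.frame with columns `name` and
#'   `certified`.
#' @export
metabolite_panel <- function(names, certified) {
  stopifnot(is.character(names), is.logical(certified),
            length(names) == length(certified))
  if (anyDuplicated(names)) stop("metabolite names must be unique")
  if (anyNA(names) || anyNA(certified)) stop("panel entries may not be NA")
  structure(data.frame(name = names, certified = certified,
                       stringsAsFactors = FALSE),
            class = c("metabolite_panel", "data.frame"))
}

#' Default 168-metabolite NMR panel
#'
#' A synthetic registry emulating the structure of a high-throughput NMR
#' biomarker platform: 98 lipoprotein-subclass lipid measures, particle
#' diameters, serum lipid totals, apolipoproteins, fatty acids, amino acids,
#' glycolysis intermediates (including lactate, pyruvate and citrate),
#' ketone bodies and fluid-balance markers. Names are representative of the
#' platform's naming style, not a verbatim roster. Exactly 27 entries are
#' flagged as the certified diagnostic subset.
#'
#' @return A [metabolite_panel()] with 168 rows.
#' @export
default_panel <- function() {
  subclasses <- c(
    "Chylomicrons and Extremely Large VLDL", "Very Large VLDL", "Large VLDL",
    "Medium VLDL", "Small VLDL", "Very Small VLDL", "IDL", "Large LDL",
    "Medium LDL", "Small LDL", "Very Large HDL", "Large HDL", "Medium HDL",
    "Small HDL")
  lipids <- c("Total Lipids", "Phospholipids", "Cholesterol",
              "Cholesteryl Esters", "Free Cholesterol", "Triglycerides")
  lipo <- as.vector(t(outer(lipids, subclasses, function(a, b)
    paste(a, "in", b))))
  particles <- paste("Concentration of", subclasses, "Particles")
  sizes <- c("VLDL Diameter", "LDL Diameter", "HDL Diameter")
  totals <- c("Total Cholesterol", "VLDL Cholesterol", "LDL Cholesterol",
              "HDL Cholesterol", "Remnant Cholesterol",
              "Clinical LDL Cholesterol", "Esterified Cholesterol",
              "Total Triglycerides", "Total Phosphoglycerides",
              "Phosphatidylcholines", "Sphingomyelins", "Total Cholines")
  apo <- c("Apolipoprotein A1", "Apolipoprotein B")
  fattyacids <- c("Total Fatty Acids", "Omega-3 Fatty Acids",
                  "Omega-6 Fatty Acids", "Docosahexaenoic Acid",
                  "Linoleic Acid", "Monounsaturated Fatty Acids",
                  "Polyunsaturated Fatty Acids", "Saturated Fatty Acids",
                  "Degree of Unsaturation", "Palmitic Acid", "Stearic Acid",
                  "Oleic Acid", "Arachidonic Acid",
                  "Conjugated Linoleic Acid")
  aminoacids <- c("Alanine", "Glutamine", "Glycine", "Histidine",
                  "Isoleucine", "Leucine", "Valine", "Phenylalanine",
                  "Tyrosine", "Total Branched-Chain Amino Acids",
                  "Serine", "Threonine", "Methionine", "Lysine", "Arginine",
                  "Proline", "Tryptophan", "Asparagine", "Aspartate",
                  "Glutamate")
  glycolysis <- c("Glucose", "Lactate", "Pyruvate", "Citrate", "Glycerol",
                  "Succinate", "Fumarate", "Malate", "alpha-Ketoglutarate")
  ketones <- c("3-Hydroxybutyrate", "Acetate", "Acetoacetate", "Acetone")
  fluid <- c("Albumin", "Creatinine", "Urea", "Uric Acid", "Phosphate",
             "Glycoprotein Acetyls")

  nm <- c(lipo, particles, sizes, totals, apo, fattyacids, aminoacids,
          glycolysis, ketones, fluid)
  stopifnot(length(nm) == 168L)

  certified <- c("Total Cholesterol", "VLDL Cholesterol",
                 "Clinical LDL Cholesterol", "HDL Cholesterol",
                 "Total Triglycerides", "Remnant Cholesterol",
                 "Apolipoprotein A1", "Apolipoprotein B",
                 "Total Fatty Acids", "Omega-3 Fatty Acids",
                 "Omega-6 Fatty Acids", "Docosahexaenoic Acid",
                 "Linoleic Acid", "Monounsaturated Fatty Acids",
                 "Polyunsaturated Fatty Acids", "Saturated Fatty Acids",
                 "Alanine", "Glutamine", "Glycine", "Histidine",
                 "Isoleucine", "Leucine", "Valine", "Phenylalanine",
                 "Tyrosine", "Glucose", "Creatinine")
  stopifnot(length(certified) == 27L, all(certified %in% nm))
  metabolite_panel(nm, nm %in% certified)
}

#' Reduced panel for small simulations
#'
#' Builds a panel of `p` generic metabolite names (`met_001`, ...) with the
#' glycolysis trio (Lactate, Pyruvate, Citrate) placed at positions
#' `resilience_at` so that small cohorts still carry named resilience
#' members. No entries are flagged certified unless `n_certified` > 0, in
#' which case the first `n_certified` names are flagged.
#'
#' @param p panel size (>= 3).
#' @param resilience_at integer positions for the trio (default first three).
#' @param n_certified number of leading entries to flag certified.
#' @return A [metabolite_panel()].
#' @export
small_panel <- function(p, resilience_at = 1:3, n_certified = 0L) {
  stopifnot(p >= 3, length(resilience_at) == 3, all(resilience_at <= p))
  nm <- sprintf("met_%03d", seq_len(p))
  nm[resilience_at] <- c("Lactate", "Pyruvate", "Citrate")
  metabolite_panel(nm, seq_len(p) <= n_certified)
}
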