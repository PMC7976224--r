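#' Bundled synthetic terminology vocabulary
#'
#' Returns the small synthetic vocabulary (concepts plus a parent-to-child
#' ancestry) that the bundled concept sets, decision trees and population
#' generators are written against. Concept identifiers, codes and names are
#' synthetic stand-ins patterned on RxNorm (drugs), LOINC (laboratory
#' measurements) and SNOMED-CT (conditions); they are not real terminology
#' codes. Class-level concepts (e.g. "nonselective beta-blocker") sit above
#' ingredient-level concepts so the descendant-assembly protocol of
#' [resolve_concept_set()] can be exercised.
#'
#' @return A list with two data frames: `concept` (columns `concept_id`,
#'   `code`, `vocabulary`, `name`) and `concept_ancestor` (columns
#'   `ancestor_concept_id`, `descendant_concept_id`, direct parent-child
#'   pairs; the transitive closure is computed at resolution time).
#' @export
#' @examples
#' v <- bundled_vocabulary()
#' head(v$concept)
bundled_vocabulary <- function() {
  rx <- function(id, code, name) data.frame(
    concept_id = id, code = code, vocabulary = "RXNORM", name = name,
    stringsAsFactors = FALSE)
  ln <- function(id, code, name) data.frame(
    concept_id = id, code = code, vocabulary = "LOINC", name = name,
    stringsAsFactors = FALSE)
  sn <- function(id, code, name) data.frame(
    concept_id = id, code = code, vocabulary = "SNOMED", name = name,
    stringsAsFactors = FALSE)

  concept <- rbind(
    rx(1001, "RX-CITALOPRAM", "citalopram"),
    rx(1010, "RX-QTCLASS", "QT interval prolonging agent"),
    rx(1011, "RX-ONDANSETRON", "ondansetron"),
    rx(1012, "RX-HALOPERIDOL", "haloperidol"),
    rx(1013, "RX-AMIODARONE", "amiodarone"),
    rx(1020, "RX-LOOPCLASS", "loop diuretic"),
    rx(1021, "RX-FUROSEMIDE", "furosemide"),
    rx(1022, "RX-BUMETANIDE", "bumetanide"),
    rx(1030, "RX-CLONIDINE", "clonidine"),
    rx(1040, "RX-BBCLASS", "beta-blocker"),
    rx(1041, "RX-BBSEL", "selective beta-blocker"),
    rx(1042, "RX-METOPROLOL", "metoprolol"),
    rx(1043, "RX-ATENOLOL", "atenolol"),
    rx(1045, "RX-BBNONSEL", "nonselective beta-blocker"),
    rx(1046, "RX-PROPRANOLOL", "propranolol"),
    rx(1047, "RX-TIMOLOL", "timolol"),
    rx(1048, "RX-NADOLOL", "nadolol"),
    rx(1050, "RX-BBALPHA", "alpha-blocking beta-blocker"),
    rx(1051, "RX-CARVEDILOL", "carvedilol"),
    rx(1052, "RX-LABETALOL", "labetalol"),
    rx(1060, "RX-EPINEPHRINE", "epinephrine"),
    rx(1070, "RX-FLUCONAZOLE", "fluconazole"),
    rx(1080, "RX-OPIOIDCLASS", "opioid analgesic"),
    rx(1081, "RX-OXYCODONE", "oxycodone"),
    rx(1082, "RX-FENTANYL", "fentanyl"),
    rx(1090, "RX-IMMCLASS", "narrow therapeutic index immunosuppressant"),
    rx(1091, "RX-TACROLIMUS", "tacrolimus"),
    rx(1092, "RX-CYCLOSPORINE", "cyclosporine"),
    rx(1093, "RX-SIROLIMUS", "sirolimus"),
    rx(1098, "RX-KSUPPCLASS", "potassium supplement"),
    rx(1099, "RX-KCL", "potassium chloride"),
    rx(1100, "RX-KCITRATE", "potassium citrate"),
    rx(1110, "RX-KSDCLASS", "potassium-sparing diuretic"),
    rx(1111, "RX-SPIRONOLACTONE", "spironolactone"),
    rx(1112, "RX-AMILORIDE", "amiloride"),
    rx(1113, "RX-TRIAMTERENE", "triamterene"),
    rx(1114, "RX-EPLERENONE", "eplerenone"),
    rx(1120, "RX-WARFARIN", "warfarin"),
    rx(1130, "RX-SSRICLASS", "selective serotonin reuptake inhibitor"),
    rx(1131, "RX-SERTRALINE", "sertraline"),
    rx(1132, "RX-FLUOXETINE", "fluoxetine"),
    rx(1140, "RX-SNRICLASS", "serotonin-norepinephrine reuptake inhibitor"),
    rx(1141, "RX-VENLAFAXINE", "venlafaxine"),
    rx(1142, "RX-DULOXETINE", "duloxetine"),
    rx(1150, "RX-TCACLASS", "tricyclic antidepressant"),
    rx(1151, "RX-AMITRIPTYLINE", "amitriptyline"),
    rx(1152, "RX-NORTRIPTYLINE", "nortriptyline"),
    rx(1161, "RX-BUPROPION", "bupropion"),
    rx(1162, "RX-MIRTAZAPINE", "mirtazapine"),
    rx(1170, "RX-NSAIDCLASS", "nonsteroidal anti-inflammatory drug"),
    rx(1171, "RX-IBUPROFEN", "ibuprofen"),
    rx(1172, "RX-NAPROXEN", "naproxen"),
    rx(1180, "RX-ASPIRIN", "aspirin"),
    rx(1190, "RX-CORTCLASS", "systemic corticosteroid"),
    rx(1191, "RX-PREDNISONE", "prednisone"),
    rx(1192, "RX-DEXAMETHASONE", "dexamethasone"),
    rx(1200, "RX-APCLASS", "antiplatelet agent"),
    rx(1201, "RX-CLOPIDOGREL", "clopidogrel"),
    rx(1202, "RX-TICAGRELOR", "ticagrelor"),
    rx(1210, "RX-SALCLASS", "salicylate"),
    rx(1211, "RX-SALSALATE", "salsalate"),
    rx(1212, "RX-CMT", "choline magnesium trisalicylate"),
    rx(1213, "RX-METHYLSAL", "methyl salicylate topical"),
    ln(2001, "LN-2823-3", "Potassium [Moles/volume] in Serum or Plasma"),
    ln(2002, "LN-QTC", "QTc interval on electrocardiogram"),
    sn(3001, "SN-MI", "myocardial infarction"),
    sn(3002, "SN-SEPSIS", "sepsis"),
    sn(3003, "SN-HF", "heart failure"),
    sn(3004, "SN-HTN", "essential hypertension"),
    sn(3010, "SN-ANAPHYLAXIS", "anaphylaxis"),
    sn(3021, "SN-UGIB", "upper gastrointestinal hemorrhage"),
    sn(3022, "SN-PUD", "peptic ulcer disease"),
    sn(3030, "SN-TECLASS", "thromboembolic condition"),
    sn(3031, "SN-AFIB", "atrial fibrillation"),
    sn(3032, "SN-DVT", "deep vein thrombosis"),
    sn(3033, "SN-PE", "pulmonary embolism")
  )

  edge <- function(parent, children) data.frame(
    ancestor_concept_id = parent, descendant_concept_id = children)
  concept_ancestor <- rbind(
    edge(1010, c(1001, 1011, 1012, 1013)),  # citalopram is itself QT-prolonging
    edge(1020, c(1021, 1022)),
    edge(1040, c(1041, 1045, 1050)),
    edge(1041, c(1042, 1043)),
    edge(1045, c(1046, 1047, 1048)),
    edge(1050, c(1051, 1052)),
    edge(1080, c(1081, 1082)),
    edge(1090, c(1091, 1092, 1093)),
    edge(1098, c(1099, 1100)),
    edge(1110, c(1111, 1112, 1113)),
    edge(1130, c(1001, 1131, 1132)),
    edge(1140, c(1141, 1142)),
    edge(1150, c(1151, 1152)),
    edge(1170, c(1171, 1172)),
    edge(1190, c(1191, 1192)),
    edge(1200, c(1201, 1202)),
    edge(1210, c(1180, 1211, 1212, 1213)),
    edge(3030, c(3031, 3032, 3033))
  )
  list(concept = concept, concept_ancestor = concept_ancestor)
}
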