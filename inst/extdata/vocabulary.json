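{
  "version": "1.0",
  "comment": "Phrase vocabulary mapping report wording to the ten study labels. Grouped source terms follow the public dataset label grouping (e.g. cardiomegaly -> Enlarged Cardiac Silhouette; several parenchymal terms also map to Opacity). Editable; point the CLI at a replacement to change it.",
  "negation_cues": ["no", "not", "without", "negative for", "clear of", "free of", "absence of"],
  "hedge_cues": ["may", "possible", "possibly", "could", "cannot exclude", "questionable"],
  "labels": {
    "Abnormal Mediastinal Contour": {
      "match_phrases": ["abnormal mediastinal contour", "enlarged cardiomediastinum", "mediastinal contour abnormality", "widened mediastinum", "mediastinal widening"],
      "unmatch_phrases": []
    },
    "Atelectasis": {
      "match_phrases": ["atelectasis", "atelectatic"],
      "unmatch_phrases": []
    },
    "Enlarged Cardiac Silhouette": {
      "match_phrases": ["enlarged cardiac silhouette", "cardiomegaly", "cardiac silhouette is enlarged", "enlarged heart"],
      "unmatch_phrases": []
    },
    "Consolidation": {
      "match_phrases": ["consolidation", "airspace consolidation", "consolidative opacity"],
      "unmatch_phrases": []
    },
    "Edema": {
      "match_phrases": ["pulmonary edema", "edema"],
      "unmatch_phrases": []
    },
    "Fracture": {
      "match_phrases": ["fracture", "fractures", "acute fracture", "rib fracture"],
      "unmatch_phrases": []
    },
    "Lung Lesion": {
      "match_phrases": ["lung nodule or mass", "lung nodule", "lung mass", "lung lesion", "nodule", "nodular opacity", "mass"],
      "unmatch_phrases": ["mass effect"]
    },
    "Opacity": {
      "match_phrases": ["pulmonary edema", "edema", "lung nodule or mass", "lung nodule", "lung mass", "nodule", "nodular opacity", "mass", "atelectasis", "atelectatic", "consolidation", "airspace consolidation", "consolidative opacity", "groundglass opacity", "ground glass opacity", "ground-glass opacity", "interstitial lung disease", "pneumonia", "lung opacity", "opacity", "opacities"],
      "unmatch_phrases": ["mass effect"]
    },
    "Pleural Abnormality": {
      "match_phrases": ["pleural abnormality", "pleural other", "pleural effusion", "pleural effusions", "effusion", "effusions", "pleural thickening"],
      "unmatch_phrases": []
    },
    "Pneumothorax": {
      "match_phrases": ["pneumothorax", "pneumothoraces"],
      "unmatch_phrases": []
    }
  }
}
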