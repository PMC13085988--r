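{
  "features": [
    {
      "name": "age",
      "display_name": "Age",
      "kind": "numerical",
      "rounding": "integer"
    },
    {
      "name": "gcs",
      "display_name": "Glasgow Coma Scale score",
      "kind": "numerical",
      "rounding": "integer"
    },
    {
      "name": "aptt",
      "display_name": "Activated partial thromboplastin time",
      "kind": "numerical",
      "unit": "seconds",
      "rounding": "one_decimal"
    },
    {
      "name": "creatinine",
      "display_name": "Creatinine",
      "kind": "numerical",
      "unit": "µmol/L",
      "rounding": "integer"
    },
    {
      "name": "sodium",
      "display_name": "Blood sodium",
      "kind": "numerical",
      "unit": "mEq/L",
      "rounding": "one_decimal"
    },
    {
      "name": "ntprobnp",
      "display_name": "NT-proBNP",
      "kind": "numerical",
      "unit": "pg/mL",
      "rounding": "integer"
    },
    {
      "name": "procalcitonin",
      "display_name": "Procalcitonin",
      "kind": "numerical",
      "unit": "ng/mL",
      "rounding": "two_decimal"
    },
    {
      "name": "crp",
      "display_name": "C-reactive protein",
      "kind": "numerical",
      "unit": "mg/L",
      "rounding": "one_decimal"
    },
    {
      "name": "wbc",
      "display_name": "White blood cells",
      "kind": "numerical",
      "unit": "k/µL",
      "rounding": "two_decimal"
    },
    {
      "name": "hematocrit",
      "display_name": "Hematocrit",
      "kind": "numerical",
      "unit": "%",
      "rounding": "one_decimal"
    },
    {
      "name": "platelets",
      "display_name": "Platelets",
      "kind": "numerical",
      "unit": "k/µL",
      "rounding": "integer"
    },
    {
      "name": "pao2",
      "display_name": "Partial pressure of oxygen (PaO2)",
      "kind": "numerical",
      "unit": "mmHg",
      "rounding": "one_decimal"
    },
    {
      "name": "fio2",
      "display_name": "Fraction of inspired oxygen (FiO2)",
      "kind": "numerical",
      "unit": "%",
      "rounding": "integer"
    },
    {
      "name": "lactic_acid",
      "display_name": "Lactic acid",
      "kind": "numerical",
      "unit": "mmol/L",
      "rounding": "one_decimal"
    },
    {
      "name": "sbp",
      "display_name": "Systolic blood pressure",
      "kind": "numerical",
      "unit": "mmHg",
      "rounding": "integer"
    },
    {
      "name": "dbp",
      "display_name": "Diastolic blood pressure",
      "kind": "numerical",
      "unit": "mmHg",
      "rounding": "integer"
    },
    {
      "name": "albumin",
      "display_name": "Albumin",
      "kind": "numerical",
      "unit": "g/L",
      "rounding": "one_decimal"
    },
    {
      "name": "bilirubin",
      "display_name": "Total bilirubin",
      "kind": "numerical",
      "unit": "µmol/L",
      "rounding": "one_decimal"
    },
    {
      "name": "pt",
      "display_name": "Prothrombin time",
      "kind": "numerical",
      "unit": "seconds",
      "rounding": "one_decimal"
    },
    {
      "name": "gender",
      "display_name": "Gender",
      "kind": "categorical",
      "categorical_levels": [
        "male",
        "female"
      ]
    }
  ],
  "label_name": "outcome",
  "label_negative_text": "survives",
  "label_positive_text": "dies",
  "system_message": "You will be given characteristics of a sepsis patient admitted to the emergency department.\nClassify the patient outcome into one of the following categories: survives, or dies.\nReturn only the name of the category, and nothing else.\nMAKE SURE your output is one of the two categories stated.",
  "entity_phrase": "Sepsis patient ->",
  "threshold_interval": [
    0.05,
    0.3
  ],
  "encoded_order": [
    "aptt",
    "creatinine",
    "sodium",
    "ntprobnp",
    "procalcitonin",
    "crp",
    "wbc",
    "hematocrit",
    "platelets",
    "pao2",
    "fio2",
    "lactic_acid",
    "sbp",
    "dbp",
    "age",
    "albumin",
    "bilirubin",
    "pt",
    "gcs",
    "gender"
  ]
}
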