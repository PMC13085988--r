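#system
You will be given characteristics of a sepsis patient admitted to the emergency department.
Classify the patient outcome into one of the following categories: survives, or dies.
Return only the name of the category, and nothing else.
MAKE SURE your output is one of the two categories stated.
#user
Age: 38, Glasgow Coma Scale score: 14, Activated partial thromboplastin time: 43.5 seconds, Creatinine: 352 µmol/L, Blood sodium: 143.3 mEq/L, NT-proBNP: 10000 pg/mL, Procalcitonin: 100.0 ng/mL, C-reactive protein: 200.0 mg/L, White blood cells: 13.69 k/µL, Hematocrit: 14.9%, Platelets: 26 k/µL, Partial pressure of oxygen (PaO2): 109.0 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 0.9 mmol/L, Systolic blood pressure: 124 mmHg, Diastolic blood pressure: 84 mmHg, Albumin: 24.2 g/L, Total bilirubin: 68.2 µmol/L, Prothrombin time: 14.8 seconds, Gender: female. Sepsis patient ->
#assistant
dies
#user
Age: 84, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 52.0 seconds, Creatinine: 220 µmol/L, Blood sodium: 145.2 mEq/L, NT-proBNP: 8264 pg/mL, Procalcitonin: 100.0 ng/mL, C-reactive protein: 155.7 mg/L, White blood cells: 16.11 k/µL, Hematocrit: 37.4%, Platelets: 42 k/µL, Partial pressure of oxygen (PaO2): 82.8 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 4.0 mmol/L, Systolic blood pressure: 101 mmHg, Diastolic blood pressure: 59 mmHg, Albumin: 29.9 g/L, Total bilirubin: 5.3 µmol/L, Prothrombin time: 16.4 seconds, Gender: male. Sepsis patient ->
#assistant
survives
#user
Age: 78, Glasgow Coma Scale score: 11, Activated partial thromboplastin time: 40.0 seconds, Creatinine: 126 µmol/L, Blood sodium: 143.4 mEq/L, NT-proBNP: 2193 pg/mL, Procalcitonin: 0.81 ng/mL, C-reactive protein: 95.4 mg/L, White blood cells: 2.06 k/µL, Hematocrit: 22.7%, Platelets: 89 k/µL, Partial pressure of oxygen (PaO2): 80.9 mmHg, Fraction of inspired oxygen (FiO2): 33%, Lactic acid: 2.7 mmol/L, Systolic blood pressure: 116 mmHg, Diastolic blood pressure: 66 mmHg, Albumin: 27.0 g/L, Total bilirubin: 13.8 µmol/L, Prothrombin time: 14.8 seconds, Gender: male. Sepsis patient ->
#assistant
survives
#user
Age: 53, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 44.1 seconds, Creatinine: 88 µmol/L, Blood sodium: 141.3 mEq/L, NT-proBNP: 1935 pg/mL, Procalcitonin: 4.05 ng/mL, C-reactive protein: 132.6 mg/L, White blood cells: 11.23 k/µL, Hematocrit: 35.2%, Platelets: 140 k/µL, Partial pressure of oxygen (PaO2): 86.0 mmHg, Fraction of inspired oxygen (FiO2): 29%, Lactic acid: 2.5 mmol/L, Systolic blood pressure: 95 mmHg, Diastolic blood pressure: 55 mmHg, Albumin: 29.6 g/L, Total bilirubin: 167.9 µmol/L, Prothrombin time: 16.7 seconds, Gender: female. Sepsis patient ->
#assistant
survives
#user
Age: 56, Glasgow Coma Scale score: 14, Activated partial thromboplastin time: 47.1 seconds, Creatinine: 53 µmol/L, Blood sodium: 131.1 mEq/L, NT-proBNP: 959 pg/mL, Procalcitonin: 11.63 ng/mL, C-reactive protein: 354.1 mg/L, White blood cells: 0.55 k/µL, Hematocrit: 24.4%, Platelets: 46 k/µL, Partial pressure of oxygen (PaO2): 143.0 mmHg, Fraction of inspired oxygen (FiO2): 33%, Lactic acid: 1.3 mmol/L, Systolic blood pressure: 92 mmHg, Diastolic blood pressure: 57 mmHg, Albumin: 28.3 g/L, Total bilirubin: 5.2 µmol/L, Prothrombin time: 14.2 seconds, Gender: female. Sepsis patient ->
#assistant
survives
#user
Age: 88, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 41.5 seconds, Creatinine: 138 µmol/L, Blood sodium: 143.2 mEq/L, NT-proBNP: 2603 pg/mL, Procalcitonin: 0.68 ng/mL, C-reactive protein: 227.5 mg/L, White blood cells: 12.94 k/µL, Hematocrit: 30.7%, Platelets: 175 k/µL, Partial pressure of oxygen (PaO2): 103.0 mmHg, Fraction of inspired oxygen (FiO2): 40%, Lactic acid: 3.4 mmol/L, Systolic blood pressure: 124 mmHg, Diastolic blood pressure: 56 mmHg, Albumin: 25.7 g/L, Total bilirubin: 115.9 µmol/L, Prothrombin time: 16.4 seconds, Gender: male. Sepsis patient ->
#assistant
survives
#user
Age: 70, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 49.1 seconds, Creatinine: 269 µmol/L, Blood sodium: 145.3 mEq/L, NT-proBNP: 5719 pg/mL, Procalcitonin: 27.29 ng/mL, C-reactive protein: 240.2 mg/L, White blood cells: 21.83 k/µL, Hematocrit: 39.3%, Platelets: 104 k/µL, Partial pressure of oxygen (PaO2): 128.0 mmHg, Fraction of inspired oxygen (FiO2): 33%, Lactic acid: 3.4 mmol/L, Systolic blood pressure: 110 mmHg, Diastolic blood pressure: 67 mmHg, Albumin: 24.8 g/L, Total bilirubin: 24.1 µmol/L, Prothrombin time: 16.8 seconds, Gender: male. Sepsis patient ->
#assistant
survives
#user
Age: 22, Glasgow Coma Scale score: 11, Activated partial thromboplastin time: 41.9 seconds, Creatinine: 57 µmol/L, Blood sodium: 139.8 mEq/L, NT-proBNP: 4968 pg/mL, Procalcitonin: 0.78 ng/mL, C-reactive protein: 138.3 mg/L, White blood cells: 8.86 k/µL, Hematocrit: 19.9%, Platelets: 199 k/µL, Partial pressure of oxygen (PaO2): 74.4 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 1.8 mmol/L, Systolic blood pressure: 108 mmHg, Diastolic blood pressure: 79 mmHg, Albumin: 27.1 g/L, Total bilirubin: 39.1 µmol/L, Prothrombin time: 14.1 seconds, Gender: female. Sepsis patient ->
#assistant
survives
#user
Age: 50, Glasgow Coma Scale score: 14, Activated partial thromboplastin time: 39.4 seconds, Creatinine: 100 µmol/L, Blood sodium: 142.8 mEq/L, NT-proBNP: 73 pg/mL, Procalcitonin: 2.06 ng/mL, C-reactive protein: 116.6 mg/L, White blood cells: 14.2 k/µL, Hematocrit: 38.9%, Platelets: 266 k/µL, Partial pressure of oxygen (PaO2): 71.8 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 1.5 mmol/L, Systolic blood pressure: 95 mmHg, Diastolic blood pressure: 51 mmHg, Albumin: 37.5 g/L, Total bilirubin: 11.3 µmol/L, Prothrombin time: 16.0 seconds, Gender: male. Sepsis patient ->
#assistant
survives
#user
Age: 63, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 46.6 seconds, Creatinine: 69 µmol/L, Blood sodium: 150.7 mEq/L, NT-proBNP: 781 pg/mL, Procalcitonin: 100.0 ng/mL, C-reactive protein: 228.4 mg/L, White blood cells: 9.37 k/µL, Hematocrit: 34.2%, Platelets: 76 k/µL, Partial pressure of oxygen (PaO2): 100.0 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 1.0 mmol/L, Systolic blood pressure: 138 mmHg, Diastolic blood pressure: 77 mmHg, Albumin: 26.8 g/L, Total bilirubin: 15.6 µmol/L, Prothrombin time: 16.5 seconds, Gender: female. Sepsis patient ->
#assistant
survives
#user
Age: 79, Glasgow Coma Scale score: 15, Activated partial thromboplastin time: 34.2 seconds, Creatinine: 166 µmol/L, Blood sodium: 139.8 mEq/L, NT-proBNP: 3012 pg/mL, Procalcitonin: 2.49 ng/mL, C-reactive protein: 200.0 mg/L, White blood cells: 19.45 k/µL, Hematocrit: 37.6%, Platelets: 181 k/µL, Partial pressure of oxygen (PaO2): 60.7 mmHg, Fraction of inspired oxygen (FiO2): 21%, Lactic acid: 1.4 mmol/L, Systolic blood pressure: 140 mmHg, Diastolic blood pressure: 60 mmHg, Albumin: 25.4 g/L, Total bilirubin: 14.7 µmol/L, Prothrombin time: 14.9 seconds, Gender: male. Sepsis patient ->
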