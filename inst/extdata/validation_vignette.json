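{
  "id": "validation-case-1",
  "category": "complicated",
  "domain": "treatment",
  "text": "A 72-year-old female patient with diabetes mellitus and hypertension presents with severe right upper quadrant pain for 4 days, high fever (39.2 °C), and confusion. Physical examination reveals diffuse abdominal tenderness with guarding and a palpable mass in the right upper quadrant. Laboratory findings show WBC 22,400/μL, CRP 24.5 mg/dL, total bilirubin 2.8 mg/dL, creatinine 2.4 mg/dL, and platelet count 89,000/μL. Blood pressure is 85/50 mmHg requiring norepinephrine infusion. Abdominal CT demonstrates a distended gallbladder with wall thickening of 8 mm, intramural gas, pericholecystic fluid collection, and multiple gallstones. CCI score is 4 and ASA-PS is IV.",
  "question": "What is the most appropriate initial management?",
  "options": {
    "A": "Emergency laparoscopic cholecystectomy",
    "B": "Early laparoscopic cholecystectomy within 72 h",
    "C": "Organ support, antibiotics, and urgent percutaneous cholecystostomy",
    "D": "Conservative treatment with antibiotics alone",
    "E": "Endoscopic gallbladder drainage"
  },
  "gold": "C"
}
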