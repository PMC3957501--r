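{
  "name": "STAR",
  "sections": [
    {
      "name": "Initial clerking",
      "max_points": 10,
      "repeat_policy": "single",
      "items": [
        {
          "id": "patient_name",
          "label": "Patient name at the top of the clerking section",
          "deduction": 1
        },
        {
          "id": "hospital_number",
          "label": "Patient hospital number",
          "deduction": 1
        },
        {
          "id": "referral_source",
          "label": "Referral source (GP, A&E, ...)",
          "deduction": 1
        },
        {
          "id": "consultant",
          "label": "Consultant in charge",
          "deduction": 1
        },
        {
          "id": "date_time",
          "label": "Date and time the patient was seen",
          "deduction": 1
        },
        {
          "id": "working_diagnosis",
          "label": "Working diagnosis",
          "deduction": 1
        },
        {
          "id": "investigations",
          "label": "Investigations ordered and results available",
          "deduction": 1
        },
        {
          "id": "management_plan",
          "label": "Initial management plan",
          "deduction": 1
        },
        {
          "id": "allergies",
          "label": "Allergies",
          "deduction": 1
        },
        {
          "id": "clinician_details",
          "label": "Name, post and bleep number of the person creating the entry",
          "deduction": 1
        }
      ]
    },
    {
      "name": "Subsequent entries",
      "max_points": 8,
      "repeat_policy": "averaged_repeat",
      "items": [
        {
          "id": "patient_details",
          "label": "Patient name and hospital number on the continuation sheet",
          "deduction": 1
        },
        {
          "id": "date_time",
          "label": "Date and time of the entry",
          "deduction": 1
        },
        {
          "id": "heading",
          "label": "An entry heading",
          "deduction": 1
        },
        {
          "id": "patient_status",
          "label": "Comment on observations or the general state of the patient",
          "deduction": 1
        },
        {
          "id": "results",
          "label": "Pertinent results",
          "deduction": 1
        },
        {
          "id": "management_plan",
          "label": "A management plan",
          "deduction": 1
        },
        {
          "id": "clinician_details",
          "label": "Signature, name, bleep number and post",
          "deduction": 1
        },
        {
          "id": "legible",
          "label": "Entry legible (two illegible words render the entry illegible)",
          "deduction": 1
        }
      ],
      "max_entries": 4
    },
    {
      "name": "Consent",
      "max_points": 7,
      "repeat_policy": "single",
      "items": [
        {
          "id": "patient_details",
          "label": "Patient name, hospital number and the date",
          "deduction": 1
        },
        {
          "id": "operation",
          "label": "Operation performed",
          "deduction": 1
        },
        {
          "id": "site_side",
          "label": "Site and side in full words",
          "deduction": 1
        },
        {
          "id": "benefits",
          "label": "Benefits of the intended procedure",
          "deduction": 1
        },
        {
          "id": "risks",
          "label": "Risks and complications",
          "deduction": 1
        },
        {
          "id": "signatures",
          "label": "Signatures of the patient and the consenting doctor",
          "deduction": 1
        },
        {
          "id": "doctor_details",
          "label": "Name, post and bleep number of the consenting doctor",
          "deduction": 1
        }
      ]
    },
    {
      "name": "Anaesthetic record",
      "max_points": 7,
      "repeat_policy": "single",
      "items": [
        {
          "id": "anaesthetist_name",
          "label": "Name of anaesthetist",
          "deduction": 1
        },
        {
          "id": "preop_assessment",
          "label": "Preoperative assessment",
          "deduction": 1
        },
        {
          "id": "drugs_doses",
          "label": "Drugs and doses given during anaesthesia",
          "deduction": 1
        },
        {
          "id": "monitoring",
          "label": "Presence of monitoring data",
          "deduction": 1
        },
        {
          "id": "iv_fluids",
          "label": "Intravenous fluids given during anaesthesia",
          "deduction": 1
        },
        {
          "id": "postop_instructions",
          "label": "Postanaesthetic instructions",
          "deduction": 1
        },
        {
          "id": "signature",
          "label": "Name and signature of the person making the entry",
          "deduction": 1
        }
      ]
    },
    {
      "name": "Operative record",
      "max_points": 9,
      "repeat_policy": "single",
      "items": [
        {
          "id": "patient_details",
          "label": "Patient name, hospital number and date of operation",
          "deduction": 1
        },
        {
          "id": "surgeon",
          "label": "Name of the operating surgeon",
          "deduction": 1
        },
        {
          "id": "postop_diagnosis",
          "label": "Diagnosis after the procedure",
          "deduction": 1
        },
        {
          "id": "findings",
          "label": "Description of operative findings",
          "deduction": 1
        },
        {
          "id": "tissues_removed",
          "label": "Details of tissues removed",
          "deduction": 1
        },
        {
          "id": "sutures",
          "label": "Details of sutures used",
          "deduction": 1
        },
        {
          "id": "prosthetics",
          "label": "Prosthetics with serial numbers if used",
          "deduction": 1
        },
        {
          "id": "postop_instructions",
          "label": "Postoperative instructions",
          "deduction": 1
        },
        {
          "id": "signature",
          "label": "Surgeon's name and signature",
          "deduction": 1
        }
      ]
    },
    {
      "name": "Discharge summary",
      "max_points": 9,
      "repeat_policy": "single",
      "items": [
        {
          "id": "patient_details",
          "label": "Patient name, hospital number and address",
          "deduction": 1
        },
        {
          "id": "dates",
          "label": "Admission and discharge dates",
          "deduction": 1
        },
        {
          "id": "consultant",
          "label": "Discharging consultant",
          "deduction": 1
        },
        {
          "id": "diagnosis",
          "label": "Diagnosis at discharge",
          "deduction": 1
        },
        {
          "id": "investigations",
          "label": "Pertinent investigations and results",
          "deduction": 1
        },
        {
          "id": "procedures",
          "label": "Operations and procedures undertaken",
          "deduction": 1
        },
        {
          "id": "complications",
          "label": "Presence or absence of complications",
          "deduction": 1
        },
        {
          "id": "medications",
          "label": "Medications on discharge",
          "deduction": 1
        },
        {
          "id": "follow_up",
          "label": "Follow-up arrangements",
          "deduction": 1
        }
      ]
    }
  ]
}
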