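# Default annotation vocabulary for telecare call corpora.
topics:
  - introduction
  - identification
  - appointments
  - telemonitoring
  - general_education
  - customized_coaching
  - related_medical_experience
  - symptom_checking
  - vitals
  - medication_management
  - lifestyle_management
  - social_chatting
  - others
speakers:
  - nurse_telecarer
  - patient
  - caregiver
  - others
symptoms:
  - breathlessness
  - swelling
  - cough
  - dizziness
  - chest_pain
  - heartbeat_and_palpitations
  - bleeding
  - headache
attributes:
  symptom: [location, frequency, extent, time, activity]
  lifestyle: [fluid_and_salt_intake, smoking, alcohol]
  vitals: [blood_pressure, weight]
dialogue_acts:
  exchanging_information: [request_inform, inform]
  understanding_information: [acknowledge, request_clarification, request_confirmation]
  performing_action: [request_action, accept_action_implicit, accept_action_explicit,
                      reject_action_implicit, reject_action_explicit]
  evaluation_of_health_condition: [evaluate, evaluate_positive, evaluate_negative]
  social_emotional: [socio_emotional]
  incomplete_dialogue_act: [back_channel, fragment, stall]
  others: [others]
concern_areas:
  - hf_symptoms
  - influenza_symptoms
  - gastrointestinal_symptoms
  - vitals
  - comorbidities
  - lifestyle_management
  - medication_management
  - others
follow_up_levels:
  - business_as_usual
  - case_review
  - call_patient
  - advise_gp_polyclinic
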