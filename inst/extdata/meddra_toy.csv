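pt_code,pt_label,hlt,hlgt,soc
10016256,Fatigue,Asthenic conditions,General system disorders NEC,General disorders and administration site conditions
10033371,Pain,Pain and discomfort NEC,General system disorders NEC,General disorders and administration site conditions
10016334,Faintness,Neurological signs and symptoms NEC,Neurological disorders NEC,Nervous system disorders
10021097,Hypothyroidism,Thyroid hypofunction disorders,Thyroid gland disorders,Endocrine disorders
10020850,Hyperthyroidism,Thyroid hyperfunction disorders,Thyroid gland disorders,Endocrine disorders
10013573,Dizziness,Neurological signs and symptoms NEC,Neurological disorders NEC,Nervous system disorders
10022437,Insomnia,Disturbances in initiating and maintaining sleep,Sleep disorders and disturbances,Psychiatric disorders
10033557,Palpitations,Cardiac signs and symptoms NEC,Cardiac disorders signs and symptoms,Cardiac disorders
10019211,Headache,Headaches NEC,Headaches,Nervous system disorders
10048061,Weight decreased,Weight and growth analyses,Physical examination topics,Investigations
10047896,Weight increased,Weight and growth analyses,Physical examination topics,Investigations
10028813,Nausea,Nausea and vomiting symptoms,Gastrointestinal signs and symptoms,Gastrointestinal disorders
10047700,Vomiting,Nausea and vomiting symptoms,Gastrointestinal signs and symptoms,Gastrointestinal disorders
10012735,Diarrhoea,Diarrhoea symptoms,Gastrointestinal motility and defaecation conditions,Gastrointestinal disorders
10010774,Constipation,Gastrointestinal atonic and hypomotility disorders,Gastrointestinal motility and defaecation conditions,Gastrointestinal disorders
10000081,Abdominal pain,Gastrointestinal and abdominal pains,Gastrointestinal signs and symptoms,Gastrointestinal disorders
10002034,Alopecia,Alopecias,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
10037844,Rash,Rashes eruptions and exanthems NEC,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
10037087,Pruritus,Pruritus NEC,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
10002855,Anxiety,Anxiety symptoms,Anxiety disorders and symptoms,Psychiatric disorders
10012378,Depression,Depressive disorders,Mood disorders and disturbances NEC,Psychiatric disorders
10022891,Irritability,Mood alterations with irritability symptoms,Mood disorders and disturbances NEC,Psychiatric disorders
10028836,Nervousness,Anxiety symptoms,Anxiety disorders and symptoms,Psychiatric disorders
10043890,Tremor,Tremor (excl congenital),Movement disorders (incl parkinsonism),Nervous system disorders
10028334,Myalgia,Muscle pains,Muscle disorders,Musculoskeletal and connective tissue disorders
10003239,Arthralgia,Joint related signs and symptoms,Joint disorders,Musculoskeletal and connective tissue disorders
10028372,Muscle spasms,Muscle related signs and symptoms NEC,Muscle disorders,Musculoskeletal and connective tissue disorders
10043521,Tachycardia,Rate and rhythm disorders NEC,Cardiac arrhythmias,Cardiac disorders
10006093,Bradycardia,Rate and rhythm disorders NEC,Cardiac arrhythmias,Cardiac disorders
10020772,Hypertension,Vascular hypertensive disorders NEC,Vascular hypertensive disorders,Vascular disorders
10021118,Hypotension,Vascular hypotensive disorders,Decreased and nonspecific blood pressure disorders and shock,Vascular disorders
10013968,Dyspnoea,Breathing abnormalities,Respiratory disorders NEC,"Respiratory, thoracic and mediastinal disorders"
10011224,Cough,Coughing and associated symptoms,Respiratory disorders NEC,"Respiratory, thoracic and mediastinal disorders"
10013781,Dry mouth,Oral dryness and saliva altered,Oral soft tissue conditions,Gastrointestinal disorders
10041349,Somnolence,Disturbances in consciousness NEC,Neurological disorders NEC,Nervous system disorders
10002646,Anorexia,Appetite disorders,Appetite and general nutritional disorders,Metabolism and nutrition disorders
10022489,Increased appetite,Appetite disorders,Appetite and general nutritional disorders,Metabolism and nutrition disorders
10043189,Swelling,Oedema NEC,General system disorders NEC,General disorders and administration site conditions
10016558,Fever,Febrile disorders,Body temperature conditions,General disorders and administration site conditions
10008531,Chest pain,Cardiac signs and symptoms NEC,Cardiac disorders signs and symptoms,Cardiac disorders
10025482,Malaise,Asthenic conditions,General system disorders NEC,General disorders and administration site conditions
10042772,Sweating increased,Apocrine and eccrine gland disorders,Skin appendage conditions,Skin and subcutaneous tissue disorders
10019063,Hair loss,Alopecias,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
10027599,Mood swings,Mood alterations NEC,Mood disorders and disturbances NEC,Psychiatric disorders
10029864,Oedema peripheral,Oedema NEC,General system disorders NEC,General disorders and administration site conditions
10047340,Vertigo,Inner ear signs and symptoms,Inner ear and VIIIth cranial nerve disorders,Ear and labyrinth disorders
10043554,Taste disturbance,Taste disturbances,Neurological disorders NEC,Nervous system disorders
10024855,Memory impairment,Memory loss (excl dementia),Mental impairment disorders,Psychiatric disorders
10010947,Confusion,Confusion and disorientation,Deliria (incl confusion),Psychiatric disorders
10034960,Photosensitivity,Photosensitivity and photodermatosis conditions,Epidermal and dermal conditions,Skin and subcutaneous tissue disorders
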