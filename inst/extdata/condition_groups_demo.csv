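diagnosis_code,condition_group
D001,Acute upper respiratory tract infection
D002,Acute upper respiratory tract infection
D003,Otitis media
D004,Otitis media
D005,Asthma
D006,Asthma
D007,Allergic Rhinitis
D008,Allergic Rhinitis
D009,Dermatitis and eczema
D010,Dermatitis and eczema
D011,Fever
D012,Constipation
D013,Headaches
D014,Migraines
D014,Headaches
D015,Sleep apnea
D016,Sleep problems
D015,Sleep problems
D017,Preventive care
D018,Preventive care
D019,Obesity
D020,Autism Spectrum Disorder
D021,Developmental disorder
D022,Seizure disorder
D023,Gastroenteritis
D024,Gastroesophageal reflux
D025,Abdominal pain
D026,"Nausea, vomiting"
D027,Urinary symptoms
D028,Fractures (excluding digits)
D029,Contusions and abrasions
D030,Lacerations
D031,Acute sprains and strains
D032,Musculoskeletal signs and symptoms
D033,"Musculoskeletal disorders, other"
D034,Sinusitis
D035,Cough
D036,Viral syndromes
D037,"Conjunctivitis, keratitis"
D038,"Deafness, hearing loss"
D039,Chronic pharyngitis and tonsillitis
D040,"ENT disorders, other"
D041,Attention deficit disorder
D042,Psychological disorders of childhood
D043,Psychologic signs and symptoms
D044,Neurologic signs and symptoms
D045,Respiratory signs and symptoms
D046,Ophthalmic signs and symptoms
D047,"Strabismus, amblyopia"
D048,Exanthems
D049,Dermatophytosis
D050,Nonfungal infections of skin and subcutaneous tissue
D051,Other endocrine disorders
D052,Disorders of lipid metabolism
D053,Acute lower respiratory tract infection
D054,Viral warts and molluscum contagiosum
D055,Administrative concerns
D056,Nonspecific laboratory abnormalities
D057,Other skin disorders
D058,Nonspecific signs and symptoms
D059,Fever
D059,Nonspecific signs and symptoms
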