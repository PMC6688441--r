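code,label,category
R74,Upper respiratory infection acute,acute_short
H81,Excessive ear wax,acute_short
L81,Other injury musculoskeletal system,acute_short
R21,Throat symptoms/complaints,acute_short
S18,Laceration/cut,acute_short
U71,Cystitis/other urinary infection,acute_moderate
R05,Cough,acute_moderate
S74,Dermatophytosis,acute_moderate
L03,Low back symptoms/complaints without radiation,acute_moderate
A04,General weakness/tiredness/ill-feeling,acute_moderate
D02,Stomach ache/stomach pain,acute_long
P06,Disturbances of sleep/insomnia,acute_long
P01,Feeling anxious/nervous/tense/inadequate,acute_long
S79,Other benign neoplasms of skin,acute_long
R81,Pneumonia,acute_long
S88,Contact dermatitis/allergic eczema,long_lasting
L99,Other disease musculoskeletal system/connective tissue,long_lasting
R97,Hayfever/allergic rhinitis,long_lasting
W11,Family planning/oral contraception,long_lasting
D12,Constipation,long_lasting
K75,Acute myocardial infarction,long_lasting
N89,Migraine,long_lasting
P76,Depressive disorder,long_lasting
N93,Carpal tunnel syndrome,long_lasting
K86,Uncomplicated hypertension,chronic
R96,Asthma,chronic
S87,Atopic dermatitis/other eczema,chronic
T93,Lipid metabolism disorder,chronic
T90,Diabetes mellitus,chronic
P70,Dementia,chronic
S91,Psoriasis,chronic
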