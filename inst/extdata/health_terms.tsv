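arthritis	disease
rheumatoid arthritis	disease
mumps	disease
measles	disease
chickenpox	disease
shingles	disease
diabetes	disease
asthma	disease
influenza	disease
pneumonia	disease
bronchitis	disease
tuberculosis	disease
hepatitis	disease
malaria	disease
meningitis	disease
eczema	disease
psoriasis	disease
anemia	disease
leukemia	disease
lymphoma	disease
melanoma	disease
epilepsy	disease
migraine	disease
glaucoma	disease
cataracts	disease
gout	disease
lupus	disease
sciatica	disease
tonsillitis	disease
appendicitis	disease
laryngitis	disease
sinusitis	disease
dermatitis	disease
tendonitis	disease
osteoporosis	disease
scoliosis	disease
hypertension	disease
hypothyroidism	disease
endometriosis	disease
fibromyalgia	disease
schizophrenia	disease
dementia	disease
parkinson disease	disease
alzheimer disease	disease
crohn disease	disease
celiac disease	disease
cystic fibrosis	disease
multiple sclerosis	disease
muscular dystrophy	disease
whooping cough	disease
scarlet fever	disease
chest pain	symptom
headache	symptom
nausea	symptom
dizziness	symptom
fever	symptom
sore throat	symptom
shortness of breath	symptom
rash	symptom
swelling	symptom
vomiting	symptom
diarrhea	symptom
insomnia	symptom
numbness	symptom
wheezing	symptom
cramps	symptom
palpitations	symptom
fainting	symptom
itching	symptom
heartburn	symptom
toothache	symptom
earache	symptom
backache	symptom
heart surgery	procedure
bypass surgery	procedure
x-ray	procedure
biopsy	procedure
chemotherapy	procedure
dialysis	procedure
transplant	procedure
vaccination	procedure
mammogram	procedure
colonoscopy	procedure
ultrasound	procedure
amputation	procedure
radiation therapy	procedure
physiotherapy	procedure
blood transfusion	procedure
appendectomy	procedure
hysterectomy	procedure
angioplasty	procedure
cesarean section	procedure
tonsillectomy	procedure
stitches	procedure
insulin	drug_generic
aspirin	drug_generic
ibuprofen	drug_generic
acetaminophen	drug_generic
penicillin	drug_generic
amoxicillin	drug_generic
morphine	drug_generic
codeine	drug_generic
warfarin	drug_generic
metformin	drug_generic
prednisone	drug_generic
fluoxetine	drug_generic
sertraline	drug_generic
lisinopril	drug_generic
atorvastatin	drug_generic
omeprazole	drug_generic
salbutamol	drug_generic
methotrexate	drug_generic
naproxen	drug_generic
gabapentin	drug_generic
tylenol	drug_trade
advil	drug_trade
motrin	drug_trade
prozac	drug_trade
zoloft	drug_trade
lipitor	drug_trade
ventolin	drug_trade
ritalin	drug_trade
valium	drug_trade
coumadin	drug_trade
glucophage	drug_trade
benadryl	drug_trade
claritin	drug_trade
paxil	drug_trade
celebrex	drug_trade
ICU	acronym
MRI	acronym
HIV	acronym
ADHD	acronym
COPD	acronym
PTSD	acronym
ECG	acronym
EKG	acronym
CT scan	acronym
IBS	acronym
therapist	specialty
surgeon	specialty
cardiologist	specialty
oncologist	specialty
psychiatrist	specialty
pediatrician	specialty
physiotherapist	specialty
radiologist	specialty
neurologist	specialty
dermatologist	specialty
midwife	specialty
paramedic	specialty
anesthesiologist	specialty
chiropractor	specialty
optometrist	specialty
blood pressure	condition
tube fed	condition
high cholesterol	condition
hearing loss	condition
kidney failure	condition
heart failure	condition
fractured hip	condition
broken wrist	condition
obesity	condition
concussion	condition
stroke	condition
seizure	condition
allergy	condition
pregnancy	condition
infection	condition
inflammation	condition
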