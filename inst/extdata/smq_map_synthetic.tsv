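pt	smq_code	smq_name	scope
Atrial fibrillation	20000049	Cardiac arrhythmias	narrow
Ventricular tachycardia	20000049	Cardiac arrhythmias	narrow
Arrhythmia	20000049	Cardiac arrhythmias	narrow
Bradycardia	20000049	Cardiac arrhythmias	narrow
Atrioventricular block	20000049	Cardiac arrhythmias	narrow
Ventricular fibrillation	20000049	Cardiac arrhythmias	narrow
Tachycardia	20000049	Cardiac arrhythmias	narrow
Cardiac failure	20000004	Cardiac failure	narrow
Cardiac failure congestive	20000004	Cardiac failure	narrow
Cardiac failure acute	20000004	Cardiac failure	narrow
Cardiogenic shock	20000004	Cardiac failure	narrow
Pulmonary oedema	20000004	Cardiac failure	narrow
Cardiomyopathy	20000150	Cardiomyopathy	narrow
Cardiomyopathy acute	20000150	Cardiomyopathy	narrow
Stress cardiomyopathy	20000150	Cardiomyopathy	narrow
Ejection fraction decreased	20000150	Cardiomyopathy	narrow
Ventricular dysfunction	20000150	Cardiomyopathy	narrow
Pulmonary embolism	20000081	Embolic and thrombotic events	narrow
Deep vein thrombosis	20000081	Embolic and thrombotic events	narrow
Embolism	20000081	Embolic and thrombotic events	narrow
Portal vein thrombosis	20000081	Embolic and thrombotic events	narrow
Thrombosis	20000081	Embolic and thrombotic events	narrow
Cerebrovascular accident	20000081	Embolic and thrombotic events	narrow
Arterial thrombosis	20000081	Embolic and thrombotic events	narrow
Hypertension	20000147	Hypertension	narrow
Hypertensive crisis	20000147	Hypertension	narrow
Blood pressure increased	20000147	Hypertension	narrow
Hypertensive emergency	20000147	Hypertension	narrow
Myocardial infarction	20000043	Ischaemic heart disease	narrow
Acute myocardial infarction	20000043	Ischaemic heart disease	narrow
Angina pectoris	20000043	Ischaemic heart disease	narrow
Acute coronary syndrome	20000043	Ischaemic heart disease	narrow
Coronary artery occlusion	20000043	Ischaemic heart disease	narrow
Myocarditis	20000239	Noninfectious myocarditis/pericarditis	narrow
Immune-mediated myocarditis	20000239	Noninfectious myocarditis/pericarditis	narrow
Autoimmune myocarditis	20000239	Noninfectious myocarditis/pericarditis	narrow
Pericarditis	20000239	Noninfectious myocarditis/pericarditis	narrow
Pericardial effusion	20000239	Noninfectious myocarditis/pericarditis	narrow
Autoimmune pericarditis	20000239	Noninfectious myocarditis/pericarditis	narrow
Pulmonary hypertension	20000130	Pulmonary hypertension	narrow
Pulmonary arterial hypertension	20000130	Pulmonary hypertension	narrow
Torsade de pointes	20000001	Torsade de pointes/QT prolongation	narrow
Electrocardiogram QT prolonged	20000001	Torsade de pointes/QT prolongation	narrow
Long QT syndrome	20000001	Torsade de pointes/QT prolongation	narrow
Ventricular tachycardia	20000001	Torsade de pointes/QT prolongation	narrow
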