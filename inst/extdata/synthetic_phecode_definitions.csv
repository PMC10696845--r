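phecode,description,category
615,Endometriosis,genitourinary
625,Excessive or frequent menstruation,genitourinary
218,Uterine leiomyoma,neoplasms
620,Ovarian cyst,genitourinary
401,Essential hypertension,circulatory system
530.11,Gastroesophageal reflux disease,digestive
785,Abdominal pain,symptoms
600,Hyperplasia of prostate,genitourinary
272.11,Hypercholesterolemia,endocrine/metabolic
272.1,Hyperlipidemia,endocrine/metabolic
710,Fibromyalgia,musculoskeletal
296.2,Depression,mental disorders
340,Migraine,neurological
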