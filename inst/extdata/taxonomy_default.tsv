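provider_type	code	label
certified_nurse_midwife	367A00000X	Advanced Practice Midwife
certified_nurse_midwife	176B00000X	Midwife
nurse_practitioner	363L00000X	Nurse Practitioner
nurse_practitioner	363LA2100X	Nurse Practitioner - Acute Care
nurse_practitioner	363LA2200X	Nurse Practitioner - Adult Health
nurse_practitioner	363LC0200X	Nurse Practitioner - Critical Care Medicine
nurse_practitioner	363LC1500X	Nurse Practitioner - Community Health
nurse_practitioner	363LF0000X	Nurse Practitioner - Family
nurse_practitioner	363LG0600X	Nurse Practitioner - Gerontology
nurse_practitioner	363LN0000X	Nurse Practitioner - Neonatal
nurse_practitioner	363LN0005X	Nurse Practitioner - Neonatal Critical Care
nurse_practitioner	363LP0200X	Nurse Practitioner - Pediatrics
nurse_practitioner	363LP0222X	Nurse Practitioner - Pediatrics Critical Care
nurse_practitioner	363LP0808X	Nurse Practitioner - Psychiatric/Mental Health
nurse_practitioner	363LP1700X	Nurse Practitioner - Perinatal
nurse_practitioner	363LP2300X	Nurse Practitioner - Primary Care
nurse_practitioner	363LS0200X	Nurse Practitioner - School
nurse_practitioner	363LW0102X	Nurse Practitioner - Womens Health
nurse_practitioner	363LX0001X	Nurse Practitioner - Obstetrics and Gynecology
nurse_practitioner	363LX0106X	Nurse Practitioner - Occupational Health
dentist	122300000X	Dentist
dentist	1223D0001X	Dentist - Dental Public Health
dentist	1223D0004X	Dentist - Dentist Anesthesiologist
dentist	1223E0200X	Dentist - Endodontics
dentist	1223G0001X	Dentist - General Practice
dentist	1223P0106X	Dentist - Oral and Maxillofacial Pathology
dentist	1223P0221X	Dentist - Pediatric Dentistry
dentist	1223P0300X	Dentist - Periodontics
dentist	1223P0700X	Dentist - Prosthodontics
dentist	1223S0112X	Dentist - Oral and Maxillofacial Surgery
dentist	1223X0008X	Dentist - Oral and Maxillofacial Radiology
dentist	1223X0400X	Dentist - Orthodontics and Dentofacial Orthopedics
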