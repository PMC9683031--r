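entity,corpus,clinician_annotations,clinician_features,algorithm_annotations,algorithm_features,match,missing,spurious,partial
Accession number,training,38,38,38,38,0,0,0,38
Excision date,training,19,57,19,57,0,0,0,19
Clinical details,training,89,234,86,258,49,7,4,33
Macroscopic details,training,134,503,136,546,51,24,30,59
Microscopic details,training,125,272,125,289,45,18,24,62
Microscopic measurements,training,170,538,170,626,85,10,12,75
Report details,training,40,103,40,103,27,0,0,13
Requestor,training,20,40,20,40,20,0,0,0
Supplementary report,training,0,0,0,0,0,0,0,0
Accession number,validation,199,199,199,199,0,0,0,199
Excision date,validation,5,15,5,15,0,0,0,5
Clinical details,validation,345,1054,330,915,37,117,101,191
Macroscopic details,validation,660,2811,752,2787,12,227,309,431
Microscopic details,validation,682,1530,624,1322,11,289,214,399
Microscopic measurements,validation,757,2433,648,3032,6,213,94,548
Report details,validation,157,172,152,167,0,43,33,119
Requestor,validation,5,10,5,10,0,0,0,5
Supplementary report,validation,10,38,18,44,0,4,12,6
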