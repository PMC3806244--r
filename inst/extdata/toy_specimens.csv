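species,date,division,collector,peak_flowering
Alpha_alba,1950-05-10,1,smith,TRUE
Alpha_alba,1951-05-12,1,smith,TRUE
Alpha_alba,1952-05-11,1,jones,TRUE
Alpha_alba,1953-05-15,1,smith,TRUE
Alpha_alba,1954-05-09,1,doe,TRUE
Alpha_alba,1955-05-14,1,smith,TRUE
Alpha_alba,1956-05-13,2,smith,TRUE
Alpha_alba,1957-05-12,2,jones,TRUE
Alpha_alba,1958-05-11,1,smith,TRUE
Alpha_alba,1959-05-16,1,smith,TRUE
Alpha_alba,1950-05-10,1,smith,TRUE
Alpha_alba,1952-05-11,1,jones,TRUE
Alpha_alba,1960-13-40,1,smith,TRUE
Alpha_alba,1961-05-20,1,doe,FALSE
Alpha_alba,1962-05-21,1,doe,FALSE
Beta_bicolor,1950-06-10,1,smith,TRUE
Beta_bicolor,1951-06-12,1,smith,TRUE
Beta_bicolor,1952-06-14,1,jones,TRUE
Beta_bicolor,1953-06-16,2,smith,TRUE
Beta_bicolor,1954-06-18,2,doe,TRUE
Beta_bicolor,1955-06-11,1,smith,TRUE
Beta_bicolor,1956-06-13,1,jones,TRUE
Beta_bicolor,1957-06-15,1,smith,TRUE
Beta_bicolor,1958-06-17,1,doe,TRUE
Beta_bicolor,1959-06-19,1,smith,FALSE
Gamma_grandis,1950-08-05,3,smith,TRUE
Gamma_grandis,1951-08-07,3,smith,TRUE
Gamma_grandis,1952-08-09,3,jones,TRUE
Gamma_grandis,1953-08-11,3,smith,TRUE
Gamma_grandis,1954-08-13,1,doe,TRUE
Gamma_grandis,1955-08-15,1,smith,TRUE
Gamma_grandis,1956-08-17,2,jones,TRUE
Gamma_grandis,1957-08-19,2,smith,TRUE
Gamma_grandis,1958-08-21,3,doe,TRUE
Gamma_grandis,1959-08-23,3,smith,TRUE
Gamma_grandis,1960-08-25,3,jones,TRUE
Gamma_grandis,1961-08-27,3,smith,FALSE
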