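RN
NATIMORTO
RECEM
NASCIDO
RECEMNASCIDO
IGNORADO
IGNORADA
DESCONHECIDO
DESCONHECIDA
UNKNOWN
NEWBORN
IGNORED
FALECIDO
FALECIDA
INDIGENTE
SEM NOME
NAO INFORMADO
NAO DECLARADO
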