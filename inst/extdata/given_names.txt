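MARIA
ANA
FRANCISCA
ANTONIA
ADRIANA
JULIANA
MARCIA
FERNANDA
PATRICIA
ALINE
SANDRA
CAMILA
AMANDA
BRUNA
JESSICA
LETICIA
JULIA
LUCIANA
VANESSA
MARIANA
GABRIELA
VERA
VITORIA
LARISSA
CLAUDIA
BEATRIZ
MARTA
DANIELA
CARLA
ALESSANDRA
ELIANE
RAFAELA
SIMONE
ROSANGELA
NATALIA
CRISTIANE
VIVIANE
ROSA
TEREZINHA
SILVIA
CAROLINA
RENATA
PRISCILA
TATIANE
MONICA
IRENE
ELAINE
TAIS
CELIA
JOSEFA
LUANA
REGINA
FATIMA
APARECIDA
SONIA
KELLY
DEBORA
MICHELE
EDNA
ROSANA
SUELI
IVONE
MARLENE
HELENA
NEUZA
LUZIA
JANAINA
THAIS
SABRINA
INGRID
PAMELA
BIANCA
CAROLINE
EDUARDA
ISABELA
LAURA
LIVIA
LORENA
MANUELA
MELISSA
NICOLE
RAQUEL
REBECA
SARA
SOFIA
VALENTINA
YASMIN
ALICE
CECILIA
CLARICE
DALVA
DIRCE
ELZA
EUNICE
GENI
ILDA
IRACEMA
IVETE
JANDIRA
LOURDES
MARINA
NAIR
NILZA
ODETE
OLGA
PALMIRA
ROSEMARY
SOLANGE
TANIA
VANIA
ZILDA
ZULMIRA
CLEIDE
DAIANE
ELISANGELA
FABIANA
GISLAINE
IONE
KARINA
LUCIMAR
MARILIA
NUBIA
JOSE
JOAO
ANTONIO
FRANCISCO
CARLOS
PAULO
PEDRO
LUCAS
LUIZ
MARCOS
GABRIEL
RAFAEL
DANIEL
MARCELO
BRUNO
EDUARDO
FELIPE
RODRIGO
MANOEL
MATEUS
ANDRE
FERNANDO
FABIO
LEONARDO
GUSTAVO
GUILHERME
LEANDRO
TIAGO
SEBASTIAO
VINICIUS
ALEXANDRE
RICARDO
DIEGO
RAIMUNDO
ADRIANO
SERGIO
CLAUDIO
GERALDO
ROBERTO
MIGUEL
JORGE
ALEX
ANDERSON
ANTONIO
JEFFERSON
MAURICIO
RENATO
ROGERIO
WAGNER
WELLINGTON
WILSON
OSVALDO
OTAVIO
NELSON
MOACIR
MILTON
JAIR
IVAN
HUGO
HELIO
GILBERTO
EVERTON
ERIC
ENZO
EMANUEL
ELIAS
EDSON
DOUGLAS
DAVI
CRISTIANO
CAIO
BENEDITO
ARTHUR
ARLINDO
AUGUSTO
BERNARDO
CESAR
CICERO
DARIO
DOMINGOS
EDGAR
ELTON
EMERSON
FABRICIO
GILSON
HEITOR
IGOR
ISAAC
IVO
JACKSON
JAIME
JOAQUIM
JONAS
JULIO
KAUA
LAERTE
LAURO
LENIN
LINO
MARIO
MOISES
MURILO
NATAN
NILTON
ORLANDO
OSCAR
PABLO
PLINIO
RAUL
ROMULO
RUBENS
SAMUEL
SAULO
SILAS
TADEU
UBIRATAN
VALDIR
VITOR
WALTER
XAVIER
YURI
ZACARIAS
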